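test_that("feature extraction reflects beat physiology", {
  sim <- clean_sim(10, seed = 1,
                   rhythm = rhythm_spec(rr_cv = 0,
                                        mix = c(NORMAL = 0.7, PVC = 0.3)))
  fid <- delineate_record(sim$record, "II")
  classes <- sim$annotations$class
  # seed 1 yields N N N PVC N PVC PVC N N N: beat 2 is a flanked normal,
  # beat 4 an interior PVC
  expect_equal(classes[4], "PVC")
  fn <- extract_features(sim$record, fid, 2)
  fp <- extract_features(sim$record, fid, 4)
  expect_length(fn, 10)
  expect_true(all(is.finite(fn)) && all(is.finite(fp)))
  expect_equal(fp[["p_flag"]], 0)
  expect_equal(fp[["p_ms"]], 0)
  expect_gte(fp[["qrs_ms"]], 1.5 * fn[["qrs_ms"]] * 0.8)
})

test_that("regular sinus rhythm gives unit RR ratios", {
  sim <- clean_sim(10, seed = 6, rhythm = rhythm_spec(rr_cv = 0))
  fid <- delineate_record(sim$record, "II")
  f <- extract_features(sim$record, fid, 5)
  expect_lt(abs(f[["prev_rr_ratio"]] - 1), 0.02)
  expect_lt(abs(f[["next_rr_ratio"]] - 1), 0.02)
})

test_that("flat or undelineated beats are rejected", {
  rec <- ecg_record(cbind(II = numeric(4000)), 360)
  fid <- data.frame(beat = 1:2, p_on = NA, p_peak = NA, p_off = NA,
                    qrs_on = c(500, 1500), r = c(520, 1520),
                    s = c(540, 1540), t_off = NA, p_present = FALSE,
                    measurable = TRUE, p_amp = NA, iso = 0)
  expect_error(extract_features(rec, fid, 1, lead = "II"), "flat")
  fid$measurable <- FALSE
  expect_error(extract_features(rec, fid, 1, lead = "II"), "not delineated")
})

test_that("fit_stump solves the 1-D toy problem exactly", {
  X <- matrix(c(1, 2, 3, 4), ncol = 1)
  y <- c(-1, -1, 1, 1)
  st <- fit_stump(X, y)
  expect_gt(st$threshold, 2)
  expect_lt(st$threshold, 3)
  expect_equal(st$left, -1)
  expect_equal(st$right, 1)
  expect_equal(st$werr, 0)
})

test_that("fit_stump degenerate cases", {
  X <- matrix(c(1, 2, 3), ncol = 1)
  st <- fit_stump(X, c(1, 1, 1))
  expect_equal(st$left, 1)
  expect_equal(st$right, 1)
  # all weight on one sample: stump reproduces that label
  st2 <- fit_stump(matrix(c(1, 2), ncol = 1), c(-1, 1), c(1, 0))
  expect_equal(predict(st2, matrix(1)), -1)
  expect_error(fit_stump(X, c(1, 1, 1), c(0, 0, 0)), "weights")
})

test_that("fit_stump matches exhaustive search on random weighted data", {
  for (s in 1:25) {
    dat <- afboost:::with_seed(100 + s, {
      m <- sample(5:60, 1)
      d <- sample(1:5, 1)
      list(X = matrix(rnorm(m * d), m, d),
           y = sample(c(-1, 1), m, replace = TRUE),
           w = runif(m, 0.01, 1))
    })
    st <- fit_stump(dat$X, dat$y, dat$w)
    or <- oracle_stump(dat$X, dat$y, dat$w)
    expect_equal(st$werr, or$err, tolerance = 1e-10)
    expect_equal(st$feature, or$feature)
  }
})

test_that("boosting drives training error to zero on separable data", {
  X <- matrix(c(1, 2, 3, 4), ncol = 1)
  y <- c(-1, -1, 1, 1)
  gb <- train_gentle_adaboost(X, y, n_iter = 2)
  expect_equal(gb$train_error[2], 0)
  expect_equal(min(which(gb$train_error == 0)), 1)  # solved in round one
  expect_equal(predict(gb, X), y)
})

test_that("one boosting round equals the single fitted stump", {
  dat <- separable_set(40, 3, seed = 7)
  gb <- train_gentle_adaboost(dat$X, dat$y, n_iter = 1)
  st <- fit_stump(dat$X, dat$y, rep(1 / 40, 40))
  expect_equal(predict(gb, dat$X, type = "score"), predict(st, dat$X))
})

test_that("boosting weights stay normalised and positive every round", {
  dat <- afboost:::with_seed(55, {
    list(X = matrix(rnorm(300), 60, 5),
         y = sample(c(-1, 1), 60, replace = TRUE))
  })
  m <- nrow(dat$X)
  w <- rep(1 / m, m)
  Fx <- numeric(m)
  for (n in 1:50) {
    st <- fit_stump(dat$X, dat$y, w)
    f <- predict(st, dat$X)
    Fx <- Fx + f
    w <- w * exp(-dat$y * f)
    w <- w / sum(w)
    expect_lt(abs(sum(w) - 1), 1e-12)
    expect_gt(min(w), 0)
  }
  # the trained object agrees with the hand-run loop
  gb <- train_gentle_adaboost(dat$X, dat$y, n_iter = 50)
  expect_equal(predict(gb, dat$X, type = "score"), Fx)
  expect_equal(gb$weights, w)
})

test_that("empirical exponential loss is non-increasing across rounds", {
  dat <- afboost:::with_seed(77, {
    list(X = matrix(rnorm(400), 80, 5),
         y = sample(c(-1, 1), 80, replace = TRUE))
  })
  gb <- train_gentle_adaboost(dat$X, dat$y, n_iter = 40)
  Fx <- numeric(80)
  loss <- numeric(40)
  for (n in 1:40) {
    Fx <- Fx + predict(gb$stumps[[n]], dat$X)
    loss[n] <- mean(exp(-dat$y * Fx))
  }
  expect_true(all(diff(loss) <= 1e-12))
})

test_that("training is invariant to permuting the sample rows", {
  dat <- afboost:::with_seed(88, {
    list(X = matrix(rnorm(200), 40, 5),
         y = sample(c(-1, 1), 40, replace = TRUE))
  })
  perm <- afboost:::with_seed(89, sample(40))
  gb1 <- train_gentle_adaboost(dat$X, dat$y, n_iter = 20)
  gb2 <- train_gentle_adaboost(dat$X[perm, ], dat$y[perm], n_iter = 20)
  grid <- matrix(rnorm(250), 50, 5)
  expect_equal(predict(gb1, grid, type = "score"),
               predict(gb2, grid, type = "score"))
})

test_that("prediction follows the documented sign convention", {
  empty <- structure(list(stumps = list(), n_iter = 0),
                     class = "gentle_adaboost")
  expect_true(all(predict(empty, matrix(rnorm(10), 5, 2)) == 1))
  st <- structure(list(feature = 1, threshold = 0, left = -1, right = 1),
                  class = "stump")
  one <- structure(list(stumps = list(st), n_iter = 1),
                   class = "gentle_adaboost")
  X <- matrix(c(-2, -1, 1, 2), ncol = 1)
  expect_equal(predict(one, X), c(-1, -1, 1, 1))
  expect_error(train_gentle_adaboost(matrix(1:4, 2), c(0, 1)), "labels")
  expect_warning(train_gentle_adaboost(matrix(1:4, ncol = 1),
                                       c(1, 1, 1, 1)), "single-class")
})

test_that("back-propagation converges on separable data, deterministically", {
  dat <- afboost:::with_seed(12, {
    X <- rbind(matrix(rnorm(60, -2), 30, 2), matrix(rnorm(60, 2), 30, 2))
    list(X = X, y = rep(c(-1, 1), each = 30))
  })
  bp <- train_backprop(dat$X, dat$y, seed = 5)
  expect_true(bp$converged)
  expect_lt(bp$epochs, 5000)
  expect_equal(predict(bp, dat$X), dat$y)
  bp2 <- train_backprop(dat$X, dat$y, seed = 5)
  expect_identical(bp$W1, bp2$W1)
  expect_identical(bp$W2, bp2$W2)
  # zero epochs: untrained network with recorded MSE
  bp0 <- train_backprop(dat$X, dat$y, max_epochs = 0, seed = 5)
  expect_equal(bp0$epochs, 0)
  expect_true(is.finite(bp0$mse))
  expect_error(train_backprop(dat$X, dat$y, hidden = 0), "hidden")
})

test_that("the benchmark report covers both models and both directions", {
  pool <- make_beat_pool(n_pvc = 30, n_normal = 80, n_other = 10, seed = 3)
  rep <- run_benchmark(pool, n_train = 60, train_pvc = 15, seeds = 0:1,
                       n_iter = 20, max_epochs = 100)
  expect_setequal(unique(rep$runs$model), c("gentleboost", "backprop"))
  expect_setequal(unique(rep$runs$direction), c("A->B", "B->A"))
  expect_equal(nrow(rep$runs), 2 * 2 * 2)
  expect_error(run_benchmark(pool, n_train = 100, train_pvc = 15,
                             seeds = 0), "exceeds")
})

test_that("uninformative features leave both models at the class prior", {
  pool <- afboost:::with_seed(9, {
    n <- 300
    y <- rep(c(-1, 1), c(60, 240))
    list(X = matrix(rnorm(n * 4), n, 4), y = y)
  })
  rep <- run_benchmark(pool, n_train = 150, train_pvc = 30, seeds = 0:1,
                       n_iter = 20, max_epochs = 100)
  prior <- 240 / 300
  expect_true(all(abs(rep$runs$accuracy - prior) < 0.12))
})
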