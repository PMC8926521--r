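test_that("cohort percentages follow half-up rounding of count ratios", {
  s <- summarize_cohort(printed_cohort())
  pct <- function(g, v) s[[g]]$binary$pct[s[[g]]$binary$variable == v]
  expect_equal(pct("AF", "male"), 48.1)          # 25 / 52
  expect_equal(pct("control", "male"), 61.1)     # 33 / 54
  expect_equal(pct("AF", "smoking"), 46.2)       # 24 / 52
  expect_equal(pct("AF", "three_vessel"), 78.8)  # 41 / 52 = 78.846 %
  expect_equal(pct("control", "three_vessel"), 79.6)
  expect_error(summarize_cohort(printed_cohort()[0, ]), "empty")
})

test_that("cohort summary reports mean and SD of continuous variables", {
  tab <- data.frame(group = rep(c("A", "B"), each = 3),
                    age = c(60, 60, 60, 50, 55, 60))
  s <- summarize_cohort(tab)
  expect_equal(s$A$continuous$sd, 0)
  expect_equal(s$B$continuous$mean, 55)
  expect_equal(s$B$continuous$sd, 5)
})

test_that("two-sample t statistics match hand-derived values", {
  # identical groups
  r0 <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # {1,2,3} vs {2,3,4}: pooled sp^2 = 1, se = sqrt(2/3)
  r1 <- two_sample_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r1$t, -1 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(r1$df, 4)
  # printed summary statistics (age): the pooled formula gives ~1.68
  r2 <- two_sample_t(list(mean = 63.87, sd = 8.85, n = 52),
                     list(mean = 61.25, sd = 7.12, n = 54))
  expect_equal(r2$t, 1.6824, tolerance = 1e-4)
  expect_equal(r2$df, 104)
  # welch variant agrees with stats::t.test on raw data
  set.seed(2)
  a <- rnorm(20); b <- rnorm(25, 0.5, 2)
  rw <- two_sample_t(a, b, variant = "welch")
  tt <- t.test(a, b)
  expect_equal(rw$t, unname(tt$statistic))
  expect_equal(rw$p, tt$p.value)
  # degenerate zero-variance convention
  expect_equal(two_sample_t(c(1, 1, 1), c(1, 1, 1))$t, 0)
})

test_that("chi-square matches the Pearson formula", {
  expect_equal(chi_square_test(matrix(c(10, 20, 10, 20), 2))$chisq, 0)
  r <- chi_square_test(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
  expect_equal(r$chisq, 20 / 3, tolerance = 1e-9)
  expect_equal(r$df, 1)
  # brute-force expected-counts oracle on random tables
  for (s in 1:10) {
    tab <- afboost:::with_seed(200 + s,
                               matrix(sample(1:40, 4, replace = TRUE), 2))
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    oracle <- sum((tab - exp_counts)^2 / exp_counts)
    expect_equal(chi_square_test(tab)$chisq, oracle, tolerance = 1e-10)
  }
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")
})

test_that("logistic fit reproduces the closed-form 2x2 odds ratio", {
  # exposed: 20 cases / 30 controls; unexposed: 10 cases / 40 controls
  tab <- data.frame(
    x = rep(c(1, 1, 0, 0), c(20, 30, 10, 40)),
    group = rep(c("AF", "control", "AF", "control"), c(20, 30, 10, 40)))
  fit <- fit_logistic(tab, "x")
  or <- fit$coefficients$or[fit$coefficients$term == "x"]
  expect_equal(or, (20 * 40) / (30 * 10), tolerance = 1e-8)
  expect_true(fit$converged)
  expect_false(fit$separation)
  ci <- fit$coefficients[fit$coefficients$term == "x", ]
  expect_true(ci$ci_lo <= ci$or && ci$or <= ci$ci_hi)
})

test_that("intercept-only fit equals the log-odds of the prevalence", {
  tab <- data.frame(group = rep(c("AF", "control"), c(25, 75)))
  fit <- fit_logistic(tab, character(0))
  expect_equal(fit$coefficients$b[1], log(0.25 / 0.75), tolerance = 1e-8)
})

test_that("logistic fit agrees with glm and flags separation", {
  tab <- afboost:::with_seed(7, {
    n <- 200
    x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
    eta <- -0.5 + 1.2 * x1 - 0.8 * x2
    data.frame(x1 = x1, x2 = x2,
               group = ifelse(rbinom(n, 1, plogis(eta)) == 1,
                              "AF", "control"))
  })
  fit <- fit_logistic(tab, c("x1", "x2"))
  ref <- stats::glm(I(group == "AF") ~ x1 + x2, binomial(), tab)
  expect_equal(fit$coefficients$b, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
  # complete separation is reported, never silent
  sep <- data.frame(x = c(rnorm(20, -3), rnorm(20, 3)),
                    group = rep(c("control", "AF"), each = 20))
  fit_sep <- fit_logistic(sep, "x")
  expect_true(fit_sep$separation)
})

test_that("trapezoidal AUC equals brute-force concordance", {
  for (s in 1:60) {
    dat <- afboost:::with_seed(300 + s, {
      n <- sample(4:120, 1)
      scores <- if (s %% 3 == 0) sample(1:6, n, replace = TRUE)
                else rnorm(n)
      pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (all(pos)) pos[1] <- FALSE
      if (!any(pos)) pos[1] <- TRUE
      list(scores = scores, pos = pos)
    })
    roc <- roc_analysis(dat$scores, dat$pos, positive = TRUE)
    expect_equal(roc$auc, oracle_auc(dat$scores, dat$pos),
                 tolerance = 1e-12)
  }
})

test_that("ROC degenerate and symmetry properties hold", {
  expect_equal(roc_analysis(c(1, 2, 3, 10, 11, 12),
                            rep(c("control", "AF"), each = 3))$auc, 1)
  expect_equal(roc_analysis(rep(2, 10),
                            rep(c("AF", "control"), 5))$auc, 0.5)
  expect_error(roc_analysis(1:5, rep("AF", 5)), "both classes")
  # AUC(s) + AUC(-s) = 1 for tie-free scores
  dat <- afboost:::with_seed(5, list(s = rnorm(50),
                                     y = rep(c("AF", "control"), 25)))
  a1 <- roc_analysis(dat$s, dat$y)$auc
  a2 <- roc_analysis(-dat$s, dat$y)$auc
  expect_equal(a1 + a2, 1, tolerance = 1e-12)
  # monotone transforms change nothing
  a3 <- roc_analysis(exp(dat$s), dat$y)$auc
  expect_equal(a1, a3, tolerance = 1e-12)
})

test_that("the Youden cutoff reproduces its own operating point", {
  for (s in 1:10) {
    dat <- afboost:::with_seed(400 + s, {
      n <- 80
      y <- rep(c("AF", "control"), each = n / 2)
      s <- rnorm(n, ifelse(y == "AF", 1, 0))
      list(scores = s, y = y)
    })
    for (dir in c("ge", "le")) {
      roc <- roc_analysis(dat$scores, dat$y, direction = dir)
      call_pos <- if (dir == "ge") dat$scores >= roc$cutoff
                  else dat$scores <= roc$cutoff
      truth <- dat$y == "AF"
      sens <- mean(call_pos[truth])
      spec <- mean(!call_pos[!truth])
      i <- which(roc$thresholds == roc$cutoff)
      expect_equal(sens, roc$sensitivity[i])
      expect_equal(spec, roc$specificity[i])
      expect_equal(roc$youden, sens + spec - 1)
    }
  }
})

test_that("AUC and cutoff agree with an established ROC implementation", {
  skip_if_not_installed("pROC")
  dat <- afboost:::with_seed(6, {
    y <- rep(c("AF", "control"), each = 60)
    list(s = rnorm(120, ifelse(y == "AF", 1.2, 0)), y = y)
  })
  ours <- roc_analysis(dat$s, dat$y)
  ref <- pROC::roc(response = dat$y, predictor = dat$s, levels = c("control", "AF"),
                   direction = "<", quiet = TRUE)
  expect_equal(ours$auc, as.numeric(ref$auc), tolerance = 1e-12)
})

test_that("diagnostic metrics compute the four printed percentages", {
  m <- diagnostic_metrics(tp = 40, fp = 5, tn = 45, fn = 10)
  expect_equal(m$sensitivity, 80.0)
  expect_equal(m$specificity, 90.0)
  expect_equal(m$ppv, 88.9)
  expect_equal(m$npv, 81.8)
  all_right <- diagnostic_metrics(10, 0, 10, 0)
  expect_true(all(c(all_right$sensitivity, all_right$specificity,
                    all_right$ppv, all_right$npv) == 100))
  none_called <- diagnostic_metrics(0, 0, 10, 5)
  expect_false(none_called$ppv_defined)
  expect_true(is.na(none_called$ppv))
  expect_error(diagnostic_metrics(0, 0, 0, 0), "at least one")
})

test_that("random predictions on balanced labels score near 50%", {
  dat <- afboost:::with_seed(17, {
    n <- 10000
    truth <- rep(c(TRUE, FALSE), each = n / 2)
    call <- sample(c(TRUE, FALSE), n, replace = TRUE)
    list(truth = truth, call = call)
  })
  m <- diagnostic_metrics(tp = sum(dat$call & dat$truth),
                          fp = sum(dat$call & !dat$truth),
                          tn = sum(!dat$call & !dat$truth),
                          fn = sum(!dat$call & dat$truth))
  expect_true(all(abs(c(m$sensitivity, m$specificity, m$ppv, m$npv) - 50) < 2))
})

test_that("cohort_analyze assembles the full clinical report", {
  tab <- generate_cohort(cohort_spec(seed = 19))
  rep <- cohort_analyze(tab)
  expect_s3_class(rep$logistic, "logistic_fit")
  expect_named(rep$markers, c("pmax", "pmin", "ptfv1"))
  expect_equal(rep$markers$ptfv1$direction, "le")
  expect_true(all(vapply(rep$markers, function(m) m$auc, numeric(1)) > 0.4))
  expect_true(is.finite(rep$markers$pmax$metrics$sensitivity))
})
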