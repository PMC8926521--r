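test_that("generate_beat handles the zero-amplitude degenerate case", {
  sh <- beat_shape("NORMAL")
  sh$waves$amp[] <- 0
  b <- generate_beat(sh)
  expect_true(all(b$x == 0))
  expect_equal(nrow(b$fiducials), 0)
})

test_that("ground-truth P duration is 2*k*sigma exactly", {
  sh <- beat_shape("NORMAL")
  sh$waves["P", "sigma"] <- 0.022
  b <- generate_beat(sh, fs = 1000, k = 2.5)
  # closed form: 2 * 2.5 * 0.022 s = 110 ms
  expect_equal((b$fiducials$p_off - b$fiducials$p_on) / 1000 * 1000, 110,
               tolerance = 1e-9)
})

test_that("PVC shape has no P fiducials and a broad QRS", {
  pvc <- generate_beat(beat_shape("PVC"))
  nrm <- generate_beat(beat_shape("NORMAL"))
  expect_true(is.na(pvc$fiducials$p_on))
  expect_true(is.na(pvc$fiducials$p_peak))
  w_pvc <- pvc$fiducials$s - pvc$fiducials$qrs_on
  w_nrm <- nrm$fiducials$s - nrm$fiducials$qrs_on
  expect_gte(w_pvc, 1.5 * w_nrm)
})

test_that("invalid beat parameters are rejected", {
  sh <- beat_shape("NORMAL")
  sh$waves["P", "sigma"] <- 0
  expect_error(beat_shape("NORMAL", waves = sh$waves), "sigma")
  expect_error(generate_beat(beat_shape("NORMAL"), fs = 100), "fs")
})

test_that("generate_record produces the requested beats and length", {
  sim <- generate_record(30, rhythm = rhythm_spec(mean_hr = 60),
                         leads = "II", fs = 360, seed = 1)
  expect_equal(nrow(sim$annotations), 30)
  dur_s <- nrow(sim$record$signal) / 360
  expect_true(abs(dur_s - 30) < 3)
  expect_error(generate_record(0), "n_beats")
  expect_error(generate_record(5, fs = 200), "fs")
})

test_that("equal seeds give bit-identical records and cohorts", {
  a <- generate_record(10, seed = 7)
  b <- generate_record(10, seed = 7)
  expect_identical(a$record$signal, b$record$signal)
  expect_identical(a$annotations, b$annotations)
  ca <- generate_cohort(cohort_spec(seed = 13))
  cb <- generate_cohort(cohort_spec(seed = 13))
  expect_identical(ca, cb)
})

test_that("realized PVC fraction stays within binomial bounds", {
  rh <- rhythm_spec(mix = c(NORMAL = 0.8, PVC = 0.2))
  sim <- generate_record(1000, rhythm = rh, leads = "II", seed = 99)
  n_pvc <- sum(sim$annotations$class == "PVC")
  expect_gte(n_pvc, 160)
  expect_lte(n_pvc, 240)
})

test_that("annotated R peaks sit at the clean-signal argmax", {
  sim <- clean_sim(12, seed = 4)
  x <- sim$clean$signal[, "II"]
  fs <- sim$fs
  for (i in seq_len(12)) {
    r <- sim$annotations$sample[i] + 1
    win <- max(1, r - round(0.1 * fs)):min(length(x), r + round(0.1 * fs))
    expect_lte(abs(win[which.max(x[win])] - r), 1)
  }
})

test_that("AF rhythm suppresses P waves and amplifies RR variability", {
  sim <- generate_record(20, rhythm = rhythm_spec(af = TRUE), leads = "II",
                         seed = 5)
  expect_true(all(is.na(sim$fiducials$p_on)))
  expect_gte(sim$rhythm$rr_cv, 0.15)
  rr <- diff(sim$r_times)
  expect_gte(stats::sd(rr) / mean(rr), 0.08)
})

test_that("cohort metric means converge to the specification", {
  spec <- cohort_spec(n_af = 10000, n_control = 10000,
                      pmax = list(af = c(130, 10), control = c(110, 10)),
                      seed = 21)
  tab <- generate_cohort(spec)
  expect_lt(abs(mean(tab$pmax[tab$group == "AF"]) - 130), 0.5)
  expect_lt(abs(mean(tab$pmax[tab$group == "control"]) - 110), 0.5)
  expect_lt(abs(stats::sd(tab$pmax[tab$group == "AF"]) - 10), 0.5)
})

test_that("degenerate cohort specifications behave as documented", {
  # identical group distributions carry no signal
  spec0 <- cohort_spec(n_af = 300, n_control = 300,
                       pmax = list(af = c(120, 10), control = c(120, 10)),
                       seed = 31)
  tab0 <- generate_cohort(spec0)
  roc <- roc_analysis(tab0$pmax, tab0$group, positive = "AF")
  expect_lt(abs(roc$auc - 0.5), 0.07)
  # zero prevalence gives an all-zero covariate column
  spec1 <- cohort_spec(prevalence = list(
    af = c(male = 0, smoking = 0.5, drinking = 0.5, diabetes = 0.5,
           hypertension = 0.5, mi = 0.5, three_vessel = 0.5),
    control = c(male = 0, smoking = 0.5, drinking = 0.5, diabetes = 0.5,
                hypertension = 0.5, mi = 0.5, three_vessel = 0.5)),
    seed = 32)
  expect_true(all(generate_cohort(spec1)$male == 0))
  expect_error(cohort_spec(n_af = 1), "n >= 2")
})

test_that("logistic-model cohorts recover the generating coefficients", {
  coef <- c(`(Intercept)` = -9.28, pmax = 0.08)
  spec <- cohort_spec(n_af = 1000, n_control = 1000, coef = coef, seed = 41)
  tab <- generate_cohort(spec)
  fit <- fit_logistic(tab, "pmax")
  b <- fit$coefficients
  est <- b$b[b$term == "pmax"]
  se <- b$se[b$term == "pmax"]
  expect_lt(abs(est - 0.08), 3 * se)
})
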