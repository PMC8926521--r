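test_that("all R peaks of a clean record are found within 10 ms", {
  sim <- clean_sim(30, seed = 1)
  r <- detect_r_peaks(sim$record, "II")
  expect_length(r, 30)
  err_ms <- abs(r - sim$annotations$sample) / sim$fs * 1000
  expect_lt(max(err_ms), 10)
})

test_that("R detection on degenerate inputs", {
  expect_equal(detect_r_peaks(ecg_record(numeric(3600), 360), lead = 1),
               integer(0))
  expect_error(detect_r_peaks(ecg_record(numeric(300), 360), lead = 1),
               "short")
})

test_that("R detection stays sensitive and precise under heavy noise", {
  sim <- generate_record(40, noise = noise_spec(white_sd = 0.15),
                         leads = "II", seed = 17)
  pre <- preprocess_record(sim$record)
  r <- detect_r_peaks(pre, "II")
  truth <- sim$annotations$sample
  tol <- 0.025 * sim$fs
  matched <- vapply(truth, function(t) any(abs(r - t) <= tol), logical(1))
  sens <- mean(matched)
  ppv <- mean(vapply(r, function(p) any(abs(truth - p) <= tol), logical(1)))
  expect_gte(sens, 0.95)
  expect_gte(ppv, 0.95)
})

test_that("clean-beat P boundaries land within 8 ms of ground truth", {
  sim <- clean_sim(10, seed = 3)
  fid <- delineate_record(sim$record, "II")
  tol <- 8 / 1000 * sim$fs
  expect_true(all(abs(fid$p_on - sim$fiducials$p_on) <= tol))
  expect_true(all(abs(fid$p_off - sim$fiducials$p_off) <= tol))
})

test_that("threshold crossings agree with the analytic crossing points", {
  # noise-free sum-of-Gaussians: onset/offset within ~1 sample of the
  # exact k-sigma decay point
  for (s in 1:4) {
    sim <- clean_sim(8, seed = s)
    fid <- delineate_record(sim$record, "II")
    exact <- analytic_p_bounds(sim, "II")
    expect_lt(max(abs(fid$p_on - exact$on)), 1.5)
    expect_lt(max(abs(fid$p_off - exact$off)), 1.5)
  }
})

test_that("PVC beats are flagged P-absent, not fabricated", {
  sim <- clean_sim(8, seed = 11,
                   rhythm = rhythm_spec(mix = c(PVC = 1)))
  fid <- delineate_record(sim$record, "II")
  expect_true(all(!fid$p_present))
  expect_true(all(is.na(fid$p_on)))
})

test_that("beats truncated by the record edge are flagged unmeasurable", {
  sim <- clean_sim(8, seed = 12)
  early <- delineate_beat(sim$record, "II", 5)
  expect_false(early$measurable)
  expect_error(delineate_beat(sim$record, "II", 10^7), "out of bounds")
})

test_that("lead P duration is the mean of three consecutive clear beats", {
  fs <- 360
  fid <- data.frame(
    beat = 1:4,
    p_on = c(0, 1000, 2000, 3000),
    p_off = c(0, 1000, 2000, 3000) + round(c(120, 108, 110, 112) / 1000 * fs),
    p_present = c(FALSE, TRUE, TRUE, TRUE),
    measurable = TRUE, p_amp = 0.2)
  rec <- ecg_record(numeric(4000), fs)
  got <- measure_lead_p_duration(rec, 1, fid)
  expect_equal(got, mean(round(c(108, 110, 112) / 1000 * fs) / fs * 1000))
  # fewer than three clear beats: lead is missing, not an error
  fid$p_present[3] <- FALSE
  expect_true(is.na(measure_lead_p_duration(rec, 1, fid)))
})

test_that("P-wave metrics assemble Pmax, Pmin and PTFV1", {
  durs <- c(I = 118.2, II = 125.7, III = 112.0, aVF = 108.5)
  m <- compute_p_metrics(durs, v1_width_s = 0.03, v1_depth_mm = 0.5)
  expect_equal(m$pmax, 125.7)
  expect_equal(m$pmin, 108.5)
  expect_equal(m$ptfv1, -0.015)
  # degenerate: all leads equal
  m2 <- compute_p_metrics(c(a = 115, b = 115, c = 115))
  expect_equal(m2$pmax, 115)
  expect_equal(m2$pmin, 115)
  expect_true(is.na(m2$ptfv1))
  expect_error(compute_p_metrics(c(a = 100)), "2 measurable leads")
})

test_that("Pmin <= per-lead mean <= Pmax on measured records", {
  sim <- clean_sim(8, seed = 13)
  pm <- measure_p_metrics(sim$record)
  d <- pm$per_lead[!is.na(pm$per_lead)]
  expect_true(pm$pmin <= mean(d) && mean(d) <= pm$pmax)
})

test_that("delineation is translation-equivariant and amplitude-invariant", {
  sim <- clean_sim(8, seed = 14)
  x <- sim$record$signal[, "II"]
  fs <- sim$fs
  shift <- 100
  rec1 <- ecg_record(x[(shift + 1):length(x)], fs)
  rec0 <- ecg_record(x[1:(length(x) - shift)], fs)
  f0 <- delineate_record(rec0, 1)
  f1 <- delineate_record(rec1, 1)
  common <- 2:(min(nrow(f0), nrow(f1)) - 1)
  # the consensus noise margin is data-dependent, so boundary indices may
  # differ by one sample between the two croppings
  for (col in c("p_on", "p_off", "r", "qrs_on"))
    expect_lte(max(abs(f0[[col]][common] - (f1[[col]][common] + shift))), 1)

  # positive scaling leaves every index unchanged
  rec2 <- ecg_record(2.5 * x, fs)
  f2 <- delineate_record(rec2, 1)
  fo <- delineate_record(ecg_record(x, fs), 1)
  expect_equal(fo$p_on, f2$p_on)
  expect_equal(fo$p_off, f2$p_off)
})

test_that("full-record metrics recover the generated per-lead truths", {
  sim <- clean_sim(8, seed = 15)
  pm <- measure_p_metrics(sim$record)
  truth <- true_p_duration_ms(sim)
  expect_true(all(abs(pm$per_lead - truth) <= 8))
  expect_lte(abs(pm$pmax - max(truth)), 8)
  expect_lte(abs(pm$pmin - min(truth)), 8)
  # V1 terminal force is negative (biphasic P by construction)
  expect_lt(pm$ptfv1, 0)
})
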