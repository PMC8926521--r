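#' Beat morphology specification
#'
#' A beat is modelled as a sum of Gaussian lobes, one per wave
#' (P, Q, R, S, T): `x(t) = sum_w a_w * exp(-(t - mu_w)^2 / (2 sigma_w^2))`,
#' with `mu_w` the centre offset from the R peak in seconds, `a_w` the
#' amplitude in mV and `sigma_w` the width parameter in seconds. The analytic
#' form makes ground truth exact: a wave's extent is defined as
#' `mu_w +/- k * sigma_w` (default `k = 2.5`), so the true P-wave duration is
#' `2 * k * sigma_P` by construction.
#'
#' Built-in classes:
#' * `NORMAL` — all five waves present; narrow QRS.
#' * `PVC` — premature ventricular contraction: no P wave, QRS width at
#'   least 1.5 x the normal QRS, discordant T.
#' * `OTHER` — supraventricular ectopic-like beat: P present but smaller and
#'   narrower, modestly reduced R.
#'
#' @param class One of `"NORMAL"`, `"PVC"`, `"OTHER"`.
#' @param waves Optional data.frame overriding the default morphology; rows
#'   named P, Q, R, S, T with columns `amp` (mV), `mu` (s, offset from R),
#'   `sigma` (s).
#' @return Object of class `beat_shape`: list with `waves` and `class`.
#' @export
beat_shape <- function(class = c("NORMAL", "PVC", "OTHER"), waves = NULL) {
  class <- match.arg(class)
  if (is.null(waves)) {
    waves <- switch(class,
      NORMAL = data.frame(
        row.names = c("P", "Q", "R", "S", "T"),
        amp   = c(0.20, -0.10, 1.20, -0.25, 0.35),
        mu    = c(-0.170, -0.035, 0.000, 0.030, 0.280),
        sigma = c(0.022, 0.008, 0.010, 0.009, 0.045)),
      PVC = data.frame(
        row.names = c("P", "Q", "R", "S", "T"),
        amp   = c(0.00, -0.05, 1.50, -0.60, -0.40),
        mu    = c(-0.170, -0.060, 0.000, 0.055, 0.300),
        sigma = c(0.022, 0.016, 0.020, 0.018, 0.060)),
      OTHER = data.frame(
        row.names = c("P", "Q", "R", "S", "T"),
        amp   = c(0.15, -0.08, 0.90, -0.20, 0.25),
        mu    = c(-0.150, -0.033, 0.000, 0.028, 0.260),
        sigma = c(0.018, 0.008, 0.010, 0.009, 0.042)))
  }
  need <- c("P", "Q", "R", "S", "T")
  if (!all(need %in% rownames(waves)) ||
      !all(c("amp", "mu", "sigma") %in% names(waves)))
    stop_invalid("`waves` must have rows P,Q,R,S,T and columns amp, mu, sigma")
  if (any(waves$sigma <= 0 & waves$amp != 0))
    stop_invalid("wave width sigma must be > 0 for every wave with non-zero amplitude")
  structure(list(waves = waves[need, ], class = class), class = "beat_shape")
}

#' Default beat shapes for the three beat classes
#' @return Named list of [beat_shape()] objects.
#' @export
default_beat_shapes <- function() {
  list(NORMAL = beat_shape("NORMAL"),
       PVC    = beat_shape("PVC"),
       OTHER  = beat_shape("OTHER"))
}

# QRS extent (s) under the k-sigma wave-extent convention: Q onset to S offset.
qrs_width_s <- function(shape, k = 2.5) {
  w <- shape$waves
  (w["S", "mu"] + k * w["S", "sigma"]) - (w["Q", "mu"] - k * w["Q", "sigma"])
}

#' Rhythm specification for record generation
#'
#' @param mean_hr Mean heart rate, beats per minute; must lie in \[30, 220\].
#' @param rr_cv Coefficient of variation of the RR interval (dimensionless).
#' @param mix Named per-class beat mixture probabilities (must sum to 1).
#' @param af Atrial-fibrillation flag: suppresses P waves and raises `rr_cv`
#'   to at least 0.15 (disorganised atrial activity has no generative
#'   definition beyond absent P waves and irregular RR).
#' @return Object of class `rhythm_spec`.
#' @export
rhythm_spec <- function(mean_hr = 70, rr_cv = 0.05,
                        mix = c(NORMAL = 1, PVC = 0, OTHER = 0),
                        af = FALSE) {
  if (mean_hr < 30 || mean_hr > 220)
    stop_invalid("mean_hr must be in [30, 220] bpm, got %g", mean_hr)
  if (abs(sum(mix) - 1) > 1e-8)
    stop_invalid("beat mixture probabilities must sum to 1")
  if (any(mix < 0)) stop_invalid("mixture probabilities must be >= 0")
  if (!all(names(mix) %in% c("NORMAL", "PVC", "OTHER")))
    stop_invalid("mixture classes must be NORMAL, PVC, OTHER")
  if (af) rr_cv <- max(rr_cv, 0.15)
  structure(list(mean_hr = mean_hr, rr_cv = rr_cv, mix = mix, af = af),
            class = "rhythm_spec")
}

#' Additive noise specification
#'
#' The generator injects exactly the artefacts the preprocessing stage is
#' built to remove: slow sinusoidal baseline wander, narrow-band power-line
#' interference (default 55 Hz, matching the notch default), and white noise.
#'
#' @param baseline_mv,baseline_hz Baseline-wander amplitude (mV) and
#'   frequency (Hz).
#' @param powerline_mv,powerline_hz Power-line amplitude (mV) and frequency
#'   (Hz, default 55).
#' @param white_sd White-noise standard deviation (mV).
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(baseline_mv = 0.10, baseline_hz = 0.30,
                       powerline_mv = 0.05, powerline_hz = 55,
                       white_sd = 0.01) {
  if (baseline_mv < 0 || powerline_mv < 0 || white_sd < 0)
    stop_invalid("noise amplitudes must be >= 0")
  structure(list(baseline_mv = baseline_mv, baseline_hz = baseline_hz,
                 powerline_mv = powerline_mv, powerline_hz = powerline_hz,
                 white_sd = white_sd),
            class = "noise_spec")
}

# Per-lead projection of the single-source beat onto the 12 leads: a plain
# scaling vector (no torso model; see vignette for what this omits).
#' Default 12-lead projection scalings
#' @return Named numeric vector over [standard_leads()].
#' @export
default_lead_projection <- function() {
  c(I = 0.6, II = 1.0, III = 0.5, aVR = -0.8, aVL = 0.4, aVF = 0.7,
    V1 = 0.5, V2 = 0.8, V3 = 1.1, V4 = 1.2, V5 = 1.0, V6 = 0.9)
}

# Per-lead multipliers of the P-wave width: they create genuine inter-lead
# P-duration dispersion so Pmax/Pmin are non-degenerate. Lead II carries the
# longest P (multiplier 1), aVL the shortest (0.85).
#' Default per-lead P-duration profile
#' @return Named numeric vector of width multipliers over [standard_leads()].
#' @export
default_p_lead_profile <- function() {
  c(I = 0.95, II = 1.00, III = 0.88, aVR = 0.92, aVL = 0.85, aVF = 0.97,
    V1 = 0.90, V2 = 0.93, V3 = 0.96, V4 = 0.98, V5 = 0.94, V6 = 0.91)
}

#' Generate a single beat with exact fiducial ground truth
#'
#' Evaluates the sum-of-Gaussians model on a window of `[-0.4, 0.5]` s
#' around the R peak and returns the waveform together with the analytic
#' fiducials. Wave extent uses the `k`-sigma convention, so the true P
#' duration equals `2 * k * sigma_P` seconds exactly.
#'
#' @param shape A [beat_shape()].
#' @param fs Sampling rate in Hz; must be >= 250 to resolve the QRS.
#' @param k Wave-extent multiplier (default 2.5).
#' @return List of class `ecg_beat`: `t` (s), `x` (mV), `fiducials`
#'   (one-row data.frame of 0-based sample indices, or zero rows when the
#'   beat is all-zero), `fs`, `k`.
#' @export
generate_beat <- function(shape, fs = 360, k = 2.5) {
  stopifnot(inherits(shape, "beat_shape"))
  if (fs < 250) stop_invalid("fs must be >= 250 Hz to resolve the QRS, got %g", fs)
  w <- shape$waves
  t <- seq(-0.4, 0.5, by = 1 / fs)
  x <- numeric(length(t))
  for (i in seq_len(nrow(w))) {
    if (w$amp[i] == 0) next
    x <- x + w$amp[i] * exp(-(t - w$mu[i])^2 / (2 * w$sigma[i]^2))
  }
  if (all(w$amp == 0)) {
    fid <- empty_fiducials()
  } else {
    idx <- function(time_s) as.integer(round((time_s - t[1]) * fs))
    p_here <- w["P", "amp"] != 0
    fid <- data.frame(
      beat = 1L, class = shape$class,
      p_on   = if (p_here) idx(w["P", "mu"] - k * w["P", "sigma"]) else NA_integer_,
      p_peak = if (p_here) idx(w["P", "mu"]) else NA_integer_,
      p_off  = if (p_here) idx(w["P", "mu"] + k * w["P", "sigma"]) else NA_integer_,
      qrs_on = idx(w["Q", "mu"] - k * w["Q", "sigma"]),
      r      = idx(0),
      s      = idx(w["S", "mu"]),
      t_off  = if (w["T", "amp"] != 0) idx(w["T", "mu"] + k * w["T", "sigma"]) else NA_integer_,
      stringsAsFactors = FALSE)
  }
  structure(list(t = t, x = x, fiducials = fid, fs = fs, k = k),
            class = "ecg_beat")
}

empty_fiducials <- function() {
  data.frame(beat = integer(), class = character(),
             p_on = integer(), p_peak = integer(), p_off = integer(),
             qrs_on = integer(), r = integer(), s = integer(),
             t_off = integer(), stringsAsFactors = FALSE)
}

#' Generate a multi-lead ECG record with ground-truth annotations
#'
#' Assembles `n_beats` sum-of-Gaussians beats on a rhythm drawn from
#' `rhythm`, projects them onto the requested leads, and adds the artefacts
#' in `noise`. All randomness flows through one seeded generator per call,
#' so equal seeds give bit-identical output.
#'
#' Lead V1's P wave is modelled as a biphasic (positive-then-negative)
#' deflection so the P terminal force is well defined: the terminal lobe has
#' configurable width (s) and depth (mV), and the total V1 P extent still
#' equals the per-lead profile value. PVC beats arrive early (0.7 x RR) with
#' a compensatory pause (1.3 x RR).
#'
#' @param n_beats Number of beats (>= 1).
#' @param rhythm A [rhythm_spec()].
#' @param shapes Named list of [beat_shape()] per class.
#' @param noise A [noise_spec()].
#' @param leads Subset of [standard_leads()] to synthesise.
#' @param lead_projection Named per-lead scaling vector.
#' @param p_duration_ms Optional target P duration (ms) in the reference
#'   lead (II); overrides `sigma_P` as `p_duration_ms / (2000 k)`.
#' @param p_lead_profile Named per-lead P-width multipliers.
#' @param v1_terminal Named vector `c(width_s=, depth_mv=)` for the negative
#'   terminal P lobe in V1. Defaults give a true PTFV1 of
#'   `-(0.03 s x 0.5 mm) = -0.015` mm·s at the 10 mm/mV gain convention.
#' @param fs Sampling rate in Hz (>= 250; default 360).
#' @param k Wave-extent multiplier.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return Object of class `ecg_sim`: `record` (noisy [ecg_record()]),
#'   `clean` (noise-free), `annotations` (data.frame `sample`, `class`;
#'   0-based R-peak sample indices), `fiducials` (per-beat 0-based indices
#'   on the reference lead), plus the generating specification.
#' @export
generate_record <- function(n_beats,
                            rhythm = rhythm_spec(),
                            shapes = default_beat_shapes(),
                            noise = noise_spec(),
                            leads = standard_leads(),
                            lead_projection = default_lead_projection(),
                            p_duration_ms = NULL,
                            p_lead_profile = default_p_lead_profile(),
                            v1_terminal = c(width_s = 0.03, depth_mv = 0.05),
                            fs = 360, k = 2.5, seed = NULL) {
  if (n_beats < 1) stop_invalid("n_beats must be >= 1")
  if (fs < 250) stop_invalid("fs must be >= 250 Hz to resolve the QRS, got %g", fs)
  stopifnot(inherits(rhythm, "rhythm_spec"), inherits(noise, "noise_spec"))
  if (!all(leads %in% names(lead_projection)))
    stop_invalid("every requested lead needs an entry in lead_projection")

  if (!is.null(p_duration_ms)) {
    sig <- p_duration_ms / 1000 / (2 * k)
    for (cl in c("NORMAL", "OTHER"))
      if (!is.null(shapes[[cl]])) shapes[[cl]]$waves["P", "sigma"] <- sig
  }
  if (isTRUE(rhythm$af)) {
    for (cl in names(shapes)) shapes[[cl]]$waves["P", "amp"] <- 0
  }

  with_seed(seed, {
    mix <- rhythm$mix[rhythm$mix > 0]
    classes <- if (length(mix) == 1L) rep(names(mix), n_beats)
               else sample(names(mix), n_beats, replace = TRUE, prob = mix)

    mean_rr <- 60 / rhythm$mean_hr
    rr <- if (n_beats > 1)
      pmin(pmax(stats::rnorm(n_beats - 1L, mean_rr, rhythm$rr_cv * mean_rr),
                0.35 * mean_rr), 2 * mean_rr)
    else numeric(0)
    # PVC prematurity and compensatory pause
    for (i in which(classes == "PVC")) {
      if (i >= 2L) rr[i - 1L] <- rr[i - 1L] * 0.7
      if (i <= length(rr)) rr[i] <- rr[i] * 1.3
    }
    r_times <- 0.5 + c(0, cumsum(rr))
    n <- ceiling((r_times[n_beats] + 0.6) * fs)
    tvec <- (seq_len(n) - 1L) / fs

    clean <- matrix(0, nrow = n, ncol = length(leads),
                    dimnames = list(NULL, leads))
    for (lead in leads) {
      proj <- lead_projection[[lead]]
      pscale <- p_lead_profile[[lead]] %||% 1
      x <- numeric(n)
      for (b in seq_len(n_beats)) {
        sh <- shapes[[classes[b]]]$waves
        i0 <- max(1L, floor((r_times[b] - 0.45) * fs) + 1L)
        i1 <- min(n, ceiling((r_times[b] + 0.55) * fs) + 1L)
        tt <- tvec[i0:i1] - r_times[b]
        seg <- numeric(length(tt))
        for (wv in rownames(sh)) {
          a <- sh[wv, "amp"]
          if (a == 0) next
          if (wv == "P") {
            if (lead == "V1") {
              seg <- seg + v1_biphasic_p(tt, a * abs(proj),
                                         sh[wv, "mu"], sh[wv, "sigma"] * pscale,
                                         v1_terminal, k)
              next
            }
            seg <- seg + a * proj *
              exp(-(tt - sh[wv, "mu"])^2 / (2 * (sh[wv, "sigma"] * pscale)^2))
          } else {
            seg <- seg + a * proj *
              exp(-(tt - sh[wv, "mu"])^2 / (2 * sh[wv, "sigma"]^2))
          }
        }
        x[i0:i1] <- x[i0:i1] + seg
      }
      clean[, lead] <- x
    }

    noisy <- clean
    for (j in seq_along(leads)) {
      ph_b <- stats::runif(1, 0, 2 * pi)
      ph_p <- stats::runif(1, 0, 2 * pi)
      wn <- stats::rnorm(n, 0, noise$white_sd)
      noisy[, j] <- noisy[, j] +
        noise$baseline_mv  * sin(2 * pi * noise$baseline_hz  * tvec + ph_b) +
        noise$powerline_mv * sin(2 * pi * noise$powerline_hz * tvec + ph_p) +
        wn
    }

    ann <- data.frame(sample = as.integer(round(r_times * fs)),
                      class = classes, stringsAsFactors = FALSE)

    ref_lead <- if ("II" %in% leads) "II" else leads[1]
    ref_scale <- p_lead_profile[[ref_lead]] %||% 1
    fid <- do.call(rbind, lapply(seq_len(n_beats), function(b) {
      sh <- shapes[[classes[b]]]$waves
      tau <- r_times[b]
      idx <- function(off) as.integer(round((tau + off) * fs))
      p_here <- sh["P", "amp"] != 0
      sp <- sh["P", "sigma"] * ref_scale
      data.frame(
        beat = b, class = classes[b],
        p_on   = if (p_here) idx(sh["P", "mu"] - k * sp) else NA_integer_,
        p_peak = if (p_here) idx(sh["P", "mu"]) else NA_integer_,
        p_off  = if (p_here) idx(sh["P", "mu"] + k * sp) else NA_integer_,
        qrs_on = idx(sh["Q", "mu"] - k * sh["Q", "sigma"]),
        r      = idx(0),
        s      = idx(sh["S", "mu"]),
        t_off  = if (sh["T", "amp"] != 0) idx(sh["T", "mu"] + k * sh["T", "sigma"]) else NA_integer_,
        stringsAsFactors = FALSE)
    }))

    structure(list(
      record = ecg_record(noisy, fs, leads),
      clean = ecg_record(clean, fs, leads),
      annotations = ann, fiducials = fid,
      r_times = r_times, classes = classes,
      shapes = shapes, rhythm = rhythm, noise = noise,
      lead_projection = lead_projection[leads],
      p_lead_profile = p_lead_profile,
      v1_terminal = v1_terminal, fs = fs, k = k,
      ref_lead = ref_lead), class = "ecg_sim")
  })
}

# Biphasic V1 P wave: positive lobe followed by a negative terminal lobe of
# configurable width/depth. Total extent is kept at mu_P +/- k*sigma_p so the
# per-lead duration ground truth still holds in V1.
v1_biphasic_p <- function(tt, pos_amp, mu_p, sigma_p, v1_terminal, k) {
  width_s <- v1_terminal[["width_s"]]
  depth_mv <- v1_terminal[["depth_mv"]]
  sig_neg <- width_s / (2 * k)
  mu_neg <- mu_p + k * sigma_p - k * sig_neg       # neg offset at P offset
  sig_pos <- 0.7 * sigma_p
  mu_pos <- mu_p - k * sigma_p + k * sig_pos       # pos onset at P onset
  pos_amp * exp(-(tt - mu_pos)^2 / (2 * sig_pos^2)) -
    depth_mv * exp(-(tt - mu_neg)^2 / (2 * sig_neg^2))
}

#' True per-lead P-wave duration of a simulated record
#'
#' Closed-form ground truth `2 k sigma_P * profile(lead)` in ms for NORMAL
#' beats of an [generate_record()] simulation; `NA` when P waves are
#' suppressed.
#' @param sim An `ecg_sim`.
#' @param lead Lead name (default: all leads in the record).
#' @return Named numeric vector of durations in ms.
#' @export
true_p_duration_ms <- function(sim, lead = sim$record$leads) {
  stopifnot(inherits(sim, "ecg_sim"))
  sh <- sim$shapes$NORMAL$waves
  if (is.null(sh) || sh["P", "amp"] == 0)
    return(stats::setNames(rep(NA_real_, length(lead)), lead))
  stats::setNames(
    2 * sim$k * sh["P", "sigma"] * 1000 *
      vapply(lead, function(l) sim$p_lead_profile[[l]] %||% 1, numeric(1)),
    lead)
}

#' Cohort generation specification
#'
#' Describes a two-group (AF vs control) synthetic cohort: group sizes,
#' per-group normal distributions of the P-wave metrics, left-atrial
#' diameter, age and weight, and per-group prevalences of the binary
#' covariates. Defaults reproduce the published post-CABG cohort structure:
#' 52 AF / 54 control patients with the printed covariate prevalences, and
#' metric separations chosen to give discrimination in the reported range
#' (Pmax AUC about 0.89, Pmin about 0.82, PTFV1 about 0.63).
#'
#' Each distribution entry is `list(af = c(mean, sd), control = c(mean, sd))`.
#'
#' @param n_af,n_control Group sizes (each >= 2).
#' @param pmax,pmin Pmax/Pmin distributions, ms.
#' @param ptfv1 PTFV1 distribution, mm·s (negative values = terminal force
#'   present).
#' @param lad Left atrial anterior-posterior diameter, mm.
#' @param age,weight Demographics (years, kg).
#' @param prevalence `list(af=, control=)` of named binary-covariate
#'   prevalences in \[0, 1\].
#' @param coef Optional named logistic coefficients (including
#'   `"(Intercept)"`) over metric columns; when supplied, outcome labels are
#'   drawn from that logistic model instead of being fixed by group.
#' @param seed Integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_af = 52, n_control = 54,
                        pmax = list(af = c(132, 9), control = c(116, 9)),
                        pmin = list(af = c(112, 8), control = c(101.5, 8)),
                        ptfv1 = list(af = c(-0.012, 0.012),
                                     control = c(-0.0065, 0.012)),
                        lad = list(af = c(38, 4), control = c(35, 4)),
                        age = list(af = c(63.87, 8.85), control = c(61.25, 7.12)),
                        weight = list(af = c(76.28, 8.27), control = c(78.15, 9.21)),
                        prevalence = list(
                          af = c(male = 25 / 52, smoking = 24 / 52,
                                 drinking = 25 / 52, diabetes = 24 / 52,
                                 hypertension = 27 / 52, mi = 25 / 52,
                                 three_vessel = 41 / 52),
                          control = c(male = 33 / 54, smoking = 25 / 54,
                                      drinking = 26 / 54, diabetes = 26 / 54,
                                      hypertension = 28 / 54, mi = 25 / 54,
                                      three_vessel = 43 / 54)),
                        coef = NULL, seed = NULL) {
  if (n_af < 2 || n_control < 2)
    stop_invalid("each group needs n >= 2 (got %d AF, %d control)", n_af, n_control)
  dists <- list(pmax = pmax, pmin = pmin, ptfv1 = ptfv1, lad = lad,
                age = age, weight = weight)
  for (nm in names(dists)) for (g in c("af", "control")) {
    d <- dists[[nm]][[g]]
    if (length(d) != 2 || d[2] <= 0)
      stop_invalid("distribution %s/%s must be c(mean, sd) with sd > 0", nm, g)
  }
  structure(c(list(n_af = n_af, n_control = n_control,
                   prevalence = prevalence, coef = coef, seed = seed), dists),
            class = "cohort_spec")
}

#' Generate a synthetic two-group patient cohort
#'
#' Draws per-patient P-wave metrics, demographics and binary covariates from
#' a [cohort_spec()]. Without `coef`, group membership is fixed (the first
#' `n_af` rows are AF) and each group's metrics come from its own
#' distribution. With `coef`, metrics for all patients come from the control
#' distributions and the AF label is drawn from the logistic model
#' `P(AF) = plogis(b0 + sum_j b_j x_j)` — the configuration used for
#' logistic parameter-recovery checks.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame of class `cohort_table` with columns `id`, `group`
#'   (`"AF"`/`"control"`), `age`, `weight`, the binary flags `male`,
#'   `smoking`, `drinking`, `diabetes`, `hypertension`, `mi`,
#'   `three_vessel`, and the metrics `pmax`, `pmin`, `ptfv1`, `lad`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    metric_cols <- c("pmax", "pmin", "ptfv1", "lad", "age", "weight")
    if (is.null(spec$coef)) {
      draw_group <- function(g, n) {
        out <- data.frame(row.names = seq_len(n))
        for (m in metric_cols) {
          d <- spec[[m]][[g]]
          out[[m]] <- stats::rnorm(n, d[1], d[2])
        }
        prev <- spec$prevalence[[g]]
        for (cv in names(prev)) out[[cv]] <- stats::rbinom(n, 1, prev[[cv]])
        out
      }
      af <- draw_group("af", spec$n_af)
      ctl <- draw_group("control", spec$n_control)
      tab <- rbind(af, ctl)
      tab$group <- rep(c("AF", "control"), c(spec$n_af, spec$n_control))
    } else {
      n <- spec$n_af + spec$n_control
      tab <- data.frame(row.names = seq_len(n))
      for (m in metric_cols) {
        d <- spec[[m]][["control"]]
        tab[[m]] <- stats::rnorm(n, d[1], d[2])
      }
      prev <- spec$prevalence[["control"]]
      for (cv in names(prev)) tab[[cv]] <- stats::rbinom(n, 1, prev[[cv]])
      vars <- setdiff(names(spec$coef), "(Intercept)")
      if (!all(vars %in% names(tab)))
        stop_invalid("logistic coefficients name unknown columns: %s",
                     paste(setdiff(vars, names(tab)), collapse = ", "))
      eta <- spec$coef[["(Intercept)"]] %||% 0
      for (v in vars) eta <- eta + spec$coef[[v]] * tab[[v]]
      tab$group <- ifelse(stats::rbinom(n, 1, stats::plogis(eta)) == 1,
                          "AF", "control")
    }
    tab <- cbind(id = seq_len(nrow(tab)), tab)
    ord <- c("id", "group", "age", "weight", "male", "smoking", "drinking",
             "diabetes", "hypertension", "mi", "three_vessel",
             "pmax", "pmin", "ptfv1", "lad")
    tab <- tab[, intersect(ord, names(tab))]
    class(tab) <- c("cohort_table", "data.frame")
    tab
  })
}
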