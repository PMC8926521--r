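# Wavelet-based R-peak detection, beat delineation and P-wave statistics.

# --- dyadic quadratic-spline wavelet transform (a trous) -------------------
# Smoothing filter h = [1,3,3,1]/8 and derivative-like wavelet filter
# g = [2,-2]; at scale 2^j the filters are upsampled by inserting 2^(j-1)-1
# zeros between taps. The wavelet coefficient at scale 2^j behaves like the
# derivative of the signal smoothed over ~2^j samples, so a peak appears as
# a positive/negative modulus-maxima pair with a zero crossing at the peak.

upsample_filter <- function(f, m) {
  if (m == 1L) return(f)
  out <- numeric((length(f) - 1L) * m + 1L)
  out[seq(1L, length(out), by = m)] <- f
  out
}

conv_causal <- function(x, f) {
  nf <- length(f)
  xp <- c(rep(x[1], nf - 1L), x)
  y <- stats::filter(xp, f, method = "convolution", sides = 1)
  as.numeric(y[nf:length(xp)])
}

shift_left <- function(x, d) {
  n <- length(x)
  if (d <= 0) return(x)
  c(x[(d + 1L):n], rep(x[n], d))
}

#' Dyadic quadratic-spline wavelet transform
#'
#' Undecimated (a trous) transform at scales `2^1 .. 2^n_scales`, with group
#' delays compensated so coefficients are aligned with the input. Used for
#' R-peak detection via modulus-maxima pairs.
#'
#' @param x Numeric signal vector.
#' @param n_scales Number of dyadic scales (default 4).
#' @return Matrix, `length(x)` rows x `n_scales` columns of coefficients.
#' @export
qspline_wavelet <- function(x, n_scales = 4L) {
  h0 <- c(1, 3, 3, 1) / 8
  g0 <- c(2, -2)
  W <- matrix(0, length(x), n_scales)
  s <- x
  for (j in seq_len(n_scales)) {
    m <- 2L^(j - 1L)
    wj <- conv_causal(s, upsample_filter(g0, m))
    # cumulative group delay of W_j is 2m - 1.5 samples
    W[, j] <- shift_left(wj, as.integer(floor(2 * m - 1.5)))
    s <- conv_causal(s, upsample_filter(h0, m))
  }
  W
}

#' Detect R peaks by wavelet modulus-maxima pairs
#'
#' Computes the quadratic-spline wavelet transform, locates opposite-signed
#' modulus maxima pairs at a QRS-band scale, places a candidate R at the
#' zero crossing between them, refines it to the local extremum of the
#' signal, and enforces a 200 ms refractory period.
#'
#' @param record An [ecg_record()] (preprocessed or clean).
#' @param lead Lead name to analyse (default `"II"`).
#' @param min_rr_s Refractory period in seconds (default 0.2).
#' @return Sorted integer vector of 0-based R-peak sample indices.
#' @export
detect_r_peaks <- function(record, lead = "II", min_rr_s = 0.2) {
  stopifnot(inherits(record, "ecg_record"))
  x <- lead_signal(record, lead)
  fs <- record$fs
  n <- length(x)
  if (n < 2 * fs)
    stop_invalid("record too short for R detection (< 2 s)")

  scale_j <- if (fs <= 500) 3L else 4L
  w <- qspline_wavelet(x, scale_j)[, scale_j]
  aw <- abs(w)
  if (max(aw) < 1e-9) return(integer(0))

  thr <- 0.25 * stats::quantile(aw, 0.995, names = FALSE)
  cand <- which(diff(sign(diff(aw))) < 0) + 1L
  cand <- cand[aw[cand] > thr]
  if (length(cand) < 2L) return(integer(0))

  peaks <- integer(0)
  strength <- numeric(0)
  max_gap <- round(0.15 * fs)
  for (kk in seq_len(length(cand) - 1L)) {
    i <- cand[kk]; jj <- cand[kk + 1L]
    if (jj - i > max_gap) next
    if (sign(w[i]) * sign(w[jj]) >= 0) next
    seg <- w[i:jj]
    zc <- which(diff(sign(seg)) != 0)
    zc <- if (length(zc)) i + zc[1] - 1L else i + which.min(abs(seg)) - 1L
    lo <- max(1L, zc - round(0.04 * fs))
    hi <- min(n, zc + round(0.04 * fs))
    base <- stats::median(x[max(1L, zc - round(0.3 * fs)):hi])
    r <- lo + which.max(abs(x[lo:hi] - base)) - 1L
    peaks <- c(peaks, r)
    strength <- c(strength, min(aw[i], aw[jj]))
  }
  if (!length(peaks)) return(integer(0))

  # refractory: greedily keep the strongest candidate within min_rr_s
  ord <- order(strength, decreasing = TRUE)
  keep <- integer(0)
  for (p in peaks[ord]) {
    if (!length(keep) || all(abs(keep - p) >= min_rr_s * fs))
      keep <- c(keep, p)
  }
  keep <- sort(unique(keep))
  # amplitude gate: T waves or noise bursts that slipped through the
  # wavelet threshold are far smaller than the consensus R amplitude
  base <- stats::median(x)
  amp <- abs(x[keep] - base)
  keep <- keep[amp >= 0.4 * stats::median(amp)]
  keep - 1L
}

#' Delineate one beat around a detected R peak
#'
#' Locates QRS onset, the S point, P peak and the P onset/offset where the
#' P deflection meets the isoelectric level, and the T offset. The
#' isoelectric ("equipotential") level is the median of a 40 ms PR-segment
#' window ending 10 ms before QRS onset. Onset/offset are placed where the
#' deflection decays to `exp(-k^2/2)` of its peak height above that level
#' (the analytic crossing point of a Gaussian lobe truncated at
#' `k` sigma). A P wave is reported absent when its peak-to-baseline
#' amplitude is below `clear_mv`; beats whose P window is truncated by the
#' record edge are flagged unmeasurable.
#'
#' @param record An [ecg_record()].
#' @param lead Lead name.
#' @param r_index 0-based R-peak sample index (from [detect_r_peaks()]).
#' @param k Wave-extent multiplier matching the generator convention.
#' @param clear_mv Minimum P amplitude (mV) for a "clear" P wave.
#' @param noise_margin Optional fixed noise margin (mV) added to the
#'   crossing level; when `NULL` it is estimated from the detrended PR
#'   segment of this beat. [delineate_record()] passes a per-lead
#'   consensus value for stability.
#' @return One-row data.frame with 0-based indices `p_on`, `p_peak`,
#'   `p_off`, `qrs_on`, `r`, `s`, `t_off`, logicals `p_present`,
#'   `measurable`, and `p_amp` (mV), `iso` (mV), `noise_margin` (mV).
#' @export
delineate_beat <- function(record, lead, r_index, k = 2.5, clear_mv = 0.05,
                           noise_margin = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  x <- lead_signal(record, lead)
  fs <- record$fs
  n <- length(x)
  r <- as.integer(r_index) + 1L
  if (r < 1L || r > n) stop_invalid("r_index %d out of bounds", r_index)

  out <- data.frame(p_on = NA_integer_, p_peak = NA_integer_,
                    p_off = NA_integer_, qrs_on = NA_integer_,
                    r = r - 1L, s = NA_integer_, t_off = NA_integer_,
                    p_present = FALSE, measurable = FALSE,
                    p_amp = NA_real_, iso = NA_real_,
                    noise_margin = NA_real_)

  if (r - round(0.36 * fs) < 1L || r + round(0.05 * fs) > n)
    return(out)  # truncated beat: unmeasurable
  out$measurable <- TRUE

  rough <- stats::median(x[(r - round(0.36 * fs)):(r - round(0.26 * fs))])
  ramp <- abs(x[r] - rough)

  # QRS onset: walk back from R until the signal stays near baseline for
  # >= 11 ms (a run guards against the zero crossing between Q and R)
  run_len <- max(4L, round(0.011 * fs))
  lo_lim <- max(1L, r - round(0.15 * fs))
  below <- abs(x[lo_lim:r] - rough) < 0.05 * ramp
  qrs_on <- NA_integer_
  run <- 0L
  for (i in rev(seq_along(below))) {
    run <- if (below[i]) run + 1L else 0L
    if (run >= run_len) { qrs_on <- lo_lim + i - 1L + run_len - 1L; break }
  }
  if (is.na(qrs_on)) qrs_on <- lo_lim
  out$qrs_on <- qrs_on - 1L

  iso_w <- x[max(1L, qrs_on - round(0.05 * fs)):max(1L, qrs_on - round(0.01 * fs))]
  iso <- stats::median(iso_w)
  out$iso <- iso

  # S point: most negative excursion just after R
  s_hi <- min(n, r + round(0.09 * fs))
  out$s <- (r + which.min(x[r:s_hi]) - 1L) - 1L

  # P search window
  w0 <- max(1L, r - round(0.32 * fs))
  w1 <- qrs_on - round(0.012 * fs)
  if (w1 <= w0) return(out)
  dev <- abs(x[w0:w1] - iso)
  # the P peak must be a local maximum strictly inside the window: a
  # deflection that only spills over the window edge (e.g. the previous
  # beat's T wave after a short RR) is not a P-wave candidate
  loc <- which(diff(sign(diff(dev))) < 0) + 1L
  if (!length(loc)) return(out)
  p_peak <- w0 + loc[which.max(dev[loc])] - 1L
  pamp <- dev[p_peak - w0 + 1L]
  out$p_amp <- pamp
  if (pamp >= clear_mv) {
    out$p_present <- TRUE
    out$p_peak <- p_peak - 1L
    # crossing level: the analytic k-sigma decay fraction, raised by a
    # noise margin estimated from the linearly detrended PR segment
    # (negligible on clean signals, where only smooth wave tails remain)
    if (is.null(noise_margin)) {
      tt <- seq_along(iso_w)
      trend <- stats::lm.fit(cbind(1, tt), iso_w)$fitted.values
      noise_margin <- 3 * stats::mad(iso_w - trend, center = 0)
    }
    out$noise_margin <- noise_margin
    level <- exp(-k^2 / 2) * pamp + noise_margin
    above <- dev > level
    # drop above-level runs shorter than 8 ms (noise blobs) unless they
    # hold the P peak itself
    min_lobe <- max(2L, round(0.008 * fs))
    rl <- rle(above)
    ends0 <- cumsum(rl$lengths)
    starts0 <- ends0 - rl$lengths + 1L
    pk <- p_peak - w0 + 1L
    blob <- rl$values & rl$lengths < min_lobe &
      !(starts0 <= pk & ends0 >= pk)
    rl$values[blob] <- FALSE
    above <- inverse.rle(rl)
    # merge sub-threshold gaps < 20 ms (biphasic P crosses the baseline)
    gap <- max(1L, round(0.02 * fs))
    rl <- rle(above)
    if (length(rl$lengths) > 1) {
      short_gap <- !rl$values & rl$lengths < gap
      short_gap[c(1L, length(rl$values))] <- FALSE
      rl$values[short_gap] <- TRUE
      rl <- rle(inverse.rle(rl))
    }
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    hit <- which(rl$values & starts <= (p_peak - w0 + 1L) &
                   ends >= (p_peak - w0 + 1L))
    if (length(hit)) {
      s0 <- starts[hit]; e0 <- ends[hit]
      if (s0 == 1L || e0 == length(dev)) {
        # the deflection touches the search-window boundary: its extent
        # cannot be certified, so the beat's P is not delineated
        out$p_present <- FALSE
        out$p_peak <- NA_integer_
        return(out)
      }
      # the crossing position is localised by a linear fit of the
      # deflection over a +/-10 ms neighbourhood of the run boundary:
      # on smooth signals this is the exact interpolated crossing, under
      # noise it averages the jitter of a single-sample comparison
      half <- max(2L, round(0.010 * fs))
      cross_fit <- function(idx0, rising) {
        win <- max(1L, idx0 - half):min(length(dev), idx0 + half)
        if (length(win) < 3L) return(idx0)
        cf <- stats::lm.fit(cbind(1, win), dev[win])$coefficients
        if (!is.finite(cf[2]) || abs(cf[2]) < 1e-12) return(idx0)
        pos <- (level - cf[1]) / cf[2]
        if ((rising && cf[2] <= 0) || (!rising && cf[2] >= 0)) return(idx0)
        min(max(pos, win[1]), win[length(win)])
      }
      out$p_on <- (w0 + as.integer(round(cross_fit(s0, TRUE))) - 1L) - 1L
      out$p_off <- (w0 + as.integer(round(cross_fit(e0, FALSE))) - 1L) - 1L
    }
  }

  # T offset: decay of the T deflection after its peak
  t0 <- min(n, r + round(0.12 * fs))
  t1 <- min(n, r + round(0.45 * fs))
  if (t1 > t0 + 5L) {
    tdev <- abs(x[t0:t1] - iso)
    tp <- which.max(tdev)
    tamp <- tdev[tp]
    if (tamp >= clear_mv) {
      lvl <- exp(-k^2 / 2) * tamp
      after <- which(tdev[tp:length(tdev)] <= lvl)
      if (length(after)) out$t_off <- (t0 + tp - 1L + after[1] - 1L) - 1L
    }
  }
  out
}

#' Delineate every beat of one lead
#'
#' Runs [detect_r_peaks()] (unless R indices are supplied) and
#' [delineate_beat()] on each beat. Delineation is done in two passes:
#' the first estimates a noise margin per beat, the second re-delineates
#' every beat with the lead's median margin, so a single disturbed PR
#' segment cannot move its own P boundaries.
#'
#' @inheritParams delineate_beat
#' @param r_peaks Optional 0-based R indices; detected on `lead` when `NULL`.
#' @return Data.frame with one row per beat (columns of [delineate_beat()]
#'   plus `beat`).
#' @export
delineate_record <- function(record, lead = "II", r_peaks = NULL,
                             k = 2.5, clear_mv = 0.05) {
  if (is.null(r_peaks)) r_peaks <- detect_r_peaks(record, lead)
  one_pass <- function(margin) {
    rows <- lapply(r_peaks, function(r)
      delineate_beat(record, lead, r, k = k, clear_mv = clear_mv,
                     noise_margin = margin))
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(out)) out <- delineate_beat(record, lead, 0L)[0, ]
    out
  }
  first <- one_pass(NULL)
  margins <- first$noise_margin[!is.na(first$noise_margin)]
  out <- if (length(margins) >= 2) one_pass(stats::median(margins))
         else first
  cbind(beat = seq_len(nrow(out)), out)
}

#' Mean P duration of one lead
#'
#' Averages the measured P duration over the first run of `n_avg`
#' consecutive clear P waves (P present, amplitude at or above `clear_mv`,
#' beat fully inside the record), following the convention of measuring
#' three clear consecutive P waves per lead. Returns `NA` — the lead is
#' marked missing, not an error — when fewer than `n_avg` consecutive clear
#' beats exist.
#'
#' @param record An [ecg_record()].
#' @param lead Lead name.
#' @param fiducials Output of [delineate_record()] for that lead.
#' @param n_avg Number of consecutive clear beats to average (default 3).
#' @param clear_mv Clear-P amplitude threshold, mV.
#' @return Mean duration in ms, or `NA_real_`.
#' @export
measure_lead_p_duration <- function(record, lead, fiducials,
                                    n_avg = 3L, clear_mv = 0.05) {
  fs <- record$fs
  ok <- fiducials$measurable & fiducials$p_present &
    !is.na(fiducials$p_amp) & fiducials$p_amp >= clear_mv &
    !is.na(fiducials$p_on) & !is.na(fiducials$p_off)
  if (sum(ok) < n_avg) return(NA_real_)
  rl <- rle(ok)
  ends <- cumsum(rl$lengths)
  hit <- which(rl$values & rl$lengths >= n_avg)
  if (!length(hit)) return(NA_real_)
  start <- ends[hit[1]] - rl$lengths[hit[1]] + 1L
  idx <- start:(start + n_avg - 1L)
  mean((fiducials$p_off[idx] - fiducials$p_on[idx]) / fs * 1000)
}

#' Measure the V1 terminal P force components
#'
#' For each clear beat in V1, measures the width (s) and depth (mm at the
#' 10 mm/mV gain convention) of the negative terminal portion of the P wave
#' (the contiguous region below the isoelectric level at the end of the P),
#' and averages over the first `n_avg` consecutive clear beats.
#'
#' @inheritParams measure_lead_p_duration
#' @param margin_mv Depth margin below the isoelectric level (mV) that the
#'   terminal lobe must exceed, guarding against residual noise.
#' @return Named vector `c(width_s=, depth_mm=)`, or `NA`s when no terminal
#'   negative deflection is found.
#' @export
measure_v1_terminal <- function(record, fiducials, lead = "V1",
                                n_avg = 3L, clear_mv = 0.05,
                                margin_mv = 0.005) {
  x <- lead_signal(record, lead)
  fs <- record$fs
  ok <- which(fiducials$measurable & fiducials$p_present &
                !is.na(fiducials$p_on) & !is.na(fiducials$p_off))
  widths <- depths <- numeric(0)
  for (b in ok) {
    i0 <- fiducials$p_peak[b] + 1L
    i1 <- fiducials$p_off[b] + 1L
    if (i1 <= i0 + 1L) next
    iso <- fiducials$iso[b]
    neg <- x[i0:i1] < iso - margin_mv
    if (!any(neg)) next
    rl <- rle(neg)
    ends <- cumsum(rl$lengths)
    last <- max(which(rl$values))
    run <- (ends[last] - rl$lengths[last] + 1L):ends[last]
    widths <- c(widths, length(run) / fs)
    depths <- c(depths, (iso - min(x[i0:i1][run])) * 10)  # mV -> mm
    if (length(widths) >= n_avg) break
  }
  if (!length(widths)) return(c(width_s = NA_real_, depth_mm = NA_real_))
  c(width_s = mean(widths), depth_mm = mean(depths))
}

#' Assemble the P-wave interval statistics
#'
#' Combines per-lead mean P durations into the dispersion markers
#' Pmax (longest) and Pmin (shortest), and the P terminal force in V1
#' `PTFV1 = -(width_s x depth_mm)` in mm·s. Calibration follows the
#' 25 mm/s paper speed and 10 mm/mV gain convention, so 0.1 mV of depth is
#' 1 mm.
#'
#' @param durations Named numeric vector of per-lead mean P durations (ms);
#'   `NA` marks a missing lead. At least two measurable leads are required.
#' @param v1_width_s,v1_depth_mm Width (s) and depth (mm) of the negative
#'   terminal P deflection in V1; both `NULL`/`NA` flags PTFV1 absent.
#' @return Object of class `p_wave_metrics`: `per_lead` (ms), `pmax`,
#'   `pmin` (ms), `ptfv1` (mm·s, `<= 0` or `NA`), `calibration`.
#' @export
compute_p_metrics <- function(durations, v1_width_s = NULL,
                              v1_depth_mm = NULL) {
  d <- durations[!is.na(durations)]
  if (length(d) < 2)
    stop_invalid("need >= 2 measurable leads, got %d", length(d))
  ptfv1 <- if (is.null(v1_width_s) || is.null(v1_depth_mm) ||
               is.na(v1_width_s) || is.na(v1_depth_mm)) NA_real_
           else -(v1_width_s * v1_depth_mm)
  structure(list(per_lead = durations,
                 pmax = max(d), pmin = min(d), ptfv1 = ptfv1,
                 calibration = c(paper_speed_mm_s = 25, gain_mm_mv = 10)),
            class = "p_wave_metrics")
}

#' @export
print.p_wave_metrics <- function(x, ...) {
  cat(sprintf("<p_wave_metrics> Pmax %.1f ms, Pmin %.1f ms, PTFV1 %s mm*s\n",
              x$pmax, x$pmin,
              if (is.na(x$ptfv1)) "absent" else sprintf("%.4f", x$ptfv1)))
  invisible(x)
}

#' Full P-wave measurement of a 12-lead record
#'
#' Detects R peaks on the reference lead, delineates every lead, measures
#' per-lead mean P durations and the V1 terminal force, and assembles the
#' [compute_p_metrics()] statistics.
#'
#' @param record A preprocessed [ecg_record()].
#' @param ref_lead Lead used for R detection (default `"II"`).
#' @param k,clear_mv,n_avg See [delineate_beat()] and
#'   [measure_lead_p_duration()].
#' @return A `p_wave_metrics` object.
#' @export
measure_p_metrics <- function(record, ref_lead = "II", k = 2.5,
                              clear_mv = 0.05, n_avg = 3L) {
  r_peaks <- detect_r_peaks(record, ref_lead)
  durs <- vapply(record$leads, function(l) {
    fid <- delineate_record(record, l, r_peaks = r_peaks, k = k,
                            clear_mv = clear_mv)
    measure_lead_p_duration(record, l, fid, n_avg = n_avg,
                            clear_mv = clear_mv)
  }, numeric(1))
  term <- c(width_s = NA_real_, depth_mm = NA_real_)
  if ("V1" %in% record$leads) {
    fid_v1 <- delineate_record(record, "V1", r_peaks = r_peaks, k = k,
                               clear_mv = clear_mv)
    term <- measure_v1_terminal(record, fid_v1, n_avg = n_avg,
                                clear_mv = clear_mv)
  }
  compute_p_metrics(durs, term[["width_s"]], term[["depth_mm"]])
}
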