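# Independent brute-force oracles and fixture builders used across tests.

# Exhaustive stump search straight from the definition: for every feature
# and every midpoint threshold, compute side responses as weighted means
# and the weighted squared error by direct summation.
oracle_stump <- function(X, y, w) {
  X <- as.matrix(X)
  w <- w / sum(w)
  cm <- sum(w * y) / sum(w)
  best <- list(feature = 1L, threshold = -Inf, left = cm, right = cm,
               err = sum(w * (y - cm)^2))
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2) next
    thrs <- (xs[-length(xs)] + xs[-1]) / 2
    for (t in thrs) {
      L <- X[, j] < t
      wl <- sum(w[L]); wr <- sum(w[!L])
      if (wl < 1e-12 || wr < 1e-12) next
      cl <- sum(w[L] * y[L]) / wl
      cr <- sum(w[!L] * y[!L]) / wr
      err <- sum(w * (y - ifelse(L, cl, cr))^2)
      if (err < best$err - 1e-15)
        best <- list(feature = j, threshold = t, left = cl, right = cr,
                     err = err)
    }
  }
  best
}

# Mann-Whitney concordance probability with ties counted one half: the
# brute-force definition of the AUC.
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Random linearly separable dataset with a clear margin.
separable_set <- function(m, d, seed) {
  afboost:::with_seed(seed, {
    w <- stats::rnorm(d)
    w <- w / sqrt(sum(w^2))
    X <- matrix(stats::rnorm(m * d), m, d)
    marg <- drop(X %*% w)
    X <- X + outer(sign(marg) * pmax(0.4 - abs(marg), 0), w)
    list(X = X, y = sign(drop(X %*% w)))
  })
}

# A clean (noise-free) simulated record; the workhorse fixture for
# delineation accuracy checks.
clean_sim <- function(n_beats = 10, seed = 1, fs = 360, ...) {
  generate_record(n_beats, noise = noise_spec(0, 0.3, 0, 55, 0),
                  fs = fs, seed = seed, ...)
}

# Analytic P-wave onset/offset (0-based fractional sample indices) for the
# reference lead of a simulation.
analytic_p_bounds <- function(sim, lead = "II") {
  sh <- sim$shapes$NORMAL$waves
  sc <- sim$p_lead_profile[[lead]]
  k <- sim$k
  list(on = (sim$r_times + sh["P", "mu"] - k * sh["P", "sigma"] * sc) * sim$fs,
       off = (sim$r_times + sh["P", "mu"] + k * sh["P", "sigma"] * sc) * sim$fs)
}

# Cohort table holding the printed covariate counts of the clinical study
# (52 AF / 54 control patients).
printed_cohort <- function() {
  flag <- function(n, k) c(rep(1, k), rep(0, n - k))
  af <- data.frame(group = "AF", male = flag(52, 25), smoking = flag(52, 24),
                   three_vessel = flag(52, 41))
  ctl <- data.frame(group = "control", male = flag(54, 33),
                    smoking = flag(54, 25), three_vessel = flag(54, 43))
  rbind(af, ctl)
}
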