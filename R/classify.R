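# Beat features, the Gentle AdaBoost classifier (regression stumps), the
# back-propagation comparator, and the train/test exchange benchmark.

#' Extract the 10-dimensional beat feature vector
#'
#' Fixed, documented feature order (the classifier input dimension is 10):
#' 1. previous RR / mean RR, 2. next RR / mean RR, 3. QRS width (onset to S
#' nadir, ms), 4. R amplitude (mV above the isoelectric level), 5. S depth
#' (mV), 6. P-present flag, 7. P duration (ms, 0 if absent), 8. PR interval
#' (ms, 0 if absent), 9. QRS area (mV·ms), 10. T amplitude (mV, signed).
#' Edge beats use the record's mean RR for the missing neighbour interval.
#'
#' @param record An [ecg_record()].
#' @param fiducials Output of [delineate_record()] for `lead` (all beats).
#' @param beat Beat row index (1-based) into `fiducials`.
#' @param lead Lead name.
#' @return Named numeric vector of length 10; always finite.
#' @export
extract_features <- function(record, fiducials, beat, lead = "II") {
  stopifnot(inherits(record, "ecg_record"))
  if (beat < 1 || beat > nrow(fiducials))
    stop_invalid("beat %d not in fiducial set (%d beats)", beat, nrow(fiducials))
  row <- fiducials[beat, ]
  if (!isTRUE(row$measurable) || is.na(row$qrs_on) || is.na(row$s))
    stop_invalid("beat %d is not delineated", beat)
  x <- lead_signal(record, lead)
  fs <- record$fs
  if (nrow(fiducials) < 2)
    stop_invalid("RR features need at least 2 beats")

  r_all <- fiducials$r
  mean_rr <- mean(diff(sort(r_all))) / fs
  prev_rr <- if (beat > 1) (row$r - fiducials$r[beat - 1]) / fs else mean_rr
  next_rr <- if (beat < nrow(fiducials)) (fiducials$r[beat + 1] - row$r) / fs
             else mean_rr

  iso <- row$iso
  r_amp <- x[row$r + 1L] - iso
  if (!is.finite(r_amp) || abs(r_amp) < 1e-6)
    stop_invalid("beat %d looks flat (no R deflection)", beat)
  s_depth <- iso - x[row$s + 1L]
  qrs_idx <- (row$qrs_on + 1L):(row$s + 1L)
  qrs_area <- sum(abs(x[qrs_idx] - iso)) / fs * 1000

  p_flag <- as.numeric(isTRUE(row$p_present))
  p_ms <- if (p_flag == 1 && !is.na(row$p_on) && !is.na(row$p_off))
    (row$p_off - row$p_on) / fs * 1000 else 0
  pr_ms <- if (p_flag == 1 && !is.na(row$p_on))
    (row$qrs_on - row$p_on) / fs * 1000 else 0

  t0 <- min(length(x), row$r + 1L + round(0.12 * fs))
  t1 <- min(length(x), row$r + 1L + round(0.40 * fs))
  tseg <- x[t0:t1] - iso
  t_amp <- tseg[which.max(abs(tseg))]

  out <- c(prev_rr_ratio = prev_rr / mean_rr,
           next_rr_ratio = next_rr / mean_rr,
           qrs_ms = (row$s - row$qrs_on) / fs * 1000,
           r_amp = r_amp, s_depth = s_depth,
           p_flag = p_flag, p_ms = p_ms, pr_ms = pr_ms,
           qrs_area = qrs_area, t_amp = t_amp)
  out[!is.finite(out)] <- 0
  out
}

#' Fit the best regression stump on weighted data
#'
#' Exact minimiser of the weighted squared error
#' `sum_i W_i (Y_i - f(X_i))^2` over all features and all midpoint
#' thresholds between consecutive distinct sorted feature values; the two
#' side responses are the weighted means of `Y` on each side (so they lie
#' in `[-1, 1]` for labels in `{-1, +1}`). Ties are broken toward the first
#' feature and the lowest threshold.
#'
#' @param X Numeric feature matrix (m x d).
#' @param y Labels in `{-1, +1}` (any numeric response is accepted).
#' @param w Non-negative sample weights; must not be all zero.
#' @return Object of class `stump`: `feature`, `threshold`, `left`,
#'   `right`, `werr` (achieved weighted squared error under weights
#'   normalised to sum 1).
#' @export
fit_stump <- function(X, y, w = rep(1 / length(y), length(y))) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (m < 2) stop_invalid("need at least 2 samples")
  if (length(y) != m || length(w) != m)
    stop_invalid("X, y, w dimensions disagree")
  if (any(w < 0) || sum(w) <= 0)
    stop_invalid("weights must be non-negative and not all zero")
  w <- w / sum(w)

  sse_total <- sum(w * y^2)
  s_all <- sum(w * y)
  eps <- 1e-300
  best <- list(feature = 1L, threshold = -Inf,
               left = s_all, right = s_all,
               werr = sse_total - s_all^2)
  best_err <- best$werr
  for (j in seq_len(ncol(X))) {
    ord <- order(X[, j])
    xv <- X[ord, j]; yv <- y[ord]; wv <- w[ord]
    cut <- which(diff(xv) > 0)
    if (!length(cut)) next
    cw <- cumsum(wv); cs <- cumsum(wv * yv)
    wl <- cw[cut]; sl <- cs[cut]
    wr <- 1 - wl; sr <- s_all - sl
    err <- sse_total - sl^2 / pmax(wl, eps) - sr^2 / pmax(wr, eps)
    # a side whose total weight has numerically vanished has no defined
    # response; such splits are not candidates
    err[wl < 1e-12 | wr < 1e-12] <- Inf
    if (all(is.infinite(err))) next
    i <- which.min(err)
    if (err[i] < best_err - 1e-15) {
      best_err <- err[i]
      thr <- (xv[cut[i]] + xv[cut[i] + 1L]) / 2
      # responses are weighted means of y, so they lie in the label hull;
      # clamp numerical noise back into it
      best <- list(feature = j, threshold = thr,
                   left = min(max(sl[i] / max(wl[i], eps), min(y)), max(y)),
                   right = min(max(sr[i] / max(wr[i], eps), min(y)), max(y)),
                   werr = err[i])
    }
  }
  structure(best, class = "stump")
}

#' @export
predict.stump <- function(object, X, ...) {
  X <- as.matrix(X)
  ifelse(X[, object$feature] < object$threshold, object$left, object$right)
}

#' Train a Gentle AdaBoost strong classifier
#'
#' The boosting loop: initialise `W_i = 1/m` and `F = 0`; each round fit the
#' weighted-least-squares regression stump `f_n` on the current weights, add
#' it to the ensemble (`F <- F + f_n`), reweight
#' `W_i <- W_i exp(-Y_i f_n(X_i))` and renormalise so `sum_i W_i = 1`.
#' The strong classifier is `sign(sum_n f_n(X))`.
#'
#' @param X Numeric feature matrix (m x d).
#' @param y Labels in `{-1, +1}` (`-1` = PVC, `+1` = other beat types).
#' @param n_iter Number of boosting rounds (default 100).
#' @return Object of class `gentle_adaboost`: `stumps` (list), `n_iter`,
#'   `train_error` (misclassification rate per round), `weights` (final
#'   normalised sample weights).
#' @export
train_gentle_adaboost <- function(X, y, n_iter = 100L) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (!all(y %in% c(-1, 1)))
    stop_invalid("labels must be exactly {-1, +1}")
  if (n_iter < 1) stop_invalid("n_iter must be >= 1")
  if (length(unique(y)) == 1L)
    warning("single-class data: training a constant classifier")

  w <- rep(1 / m, m)
  Fx <- numeric(m)
  stumps <- vector("list", n_iter)
  train_error <- numeric(n_iter)
  for (n in seq_len(n_iter)) {
    st <- fit_stump(X, y, w)
    f <- predict(st, X)
    Fx <- Fx + f
    stumps[[n]] <- st
    w <- w * exp(-y * f)
    w <- w / sum(w)
    train_error[n] <- mean(sign_plus(Fx) != y)
  }
  structure(list(stumps = stumps, n_iter = n_iter,
                 train_error = train_error, weights = w),
            class = "gentle_adaboost")
}

# sign with the documented tie rule: F = 0 predicts +1 (the non-PVC
# majority class).
sign_plus <- function(f) ifelse(f >= 0, 1, -1)

#' Predict with a Gentle AdaBoost classifier
#'
#' @param object A [train_gentle_adaboost()] fit.
#' @param X Feature matrix with the training dimensionality.
#' @param type `"class"` for labels in `{-1, +1}` (`F = 0` maps to `+1`),
#'   `"score"` for the raw ensemble sum `F(X)`.
#' @param ... Unused.
#' @return Numeric vector of labels or scores.
#' @export
predict.gentle_adaboost <- function(object, X, type = c("class", "score"),
                                    ...) {
  type <- match.arg(type)
  X <- as.matrix(X)
  d_needed <- max(vapply(object$stumps, function(s) as.numeric(s$feature),
                         numeric(1)), 1)
  if (ncol(X) < d_needed)
    stop_invalid("feature matrix has %d columns; classifier uses feature %d",
                 ncol(X), d_needed)
  score <- numeric(nrow(X))
  for (st in object$stumps) score <- score + predict(st, X)
  if (type == "score") score else sign_plus(score)
}

#' Train the back-propagation comparator network
#'
#' A single-hidden-layer perceptron with logistic units, 10 inputs and 2
#' one-hot outputs (node 1 = PVC, node 2 = other), trained by plain
#' full-batch gradient descent on the mean squared error — deliberately the
#' minimal textbook algorithm, with no momentum, adaptive step or input
#' standardisation, because it is the comparator whose behaviour the
#' benchmark contrasts with boosting. Training stops when the MSE reaches
#' `target_mse` (default 0.002) or at `max_epochs`. The same seed always
#' yields identical final weights.
#'
#' @param X Feature matrix (m x d), used as-is.
#' @param y Labels in `{-1, +1}`.
#' @param hidden Hidden-layer size (>= 1; default 10).
#' @param lr Learning rate (default 0.2).
#' @param target_mse Stopping mean squared error (default 0.002).
#' @param max_epochs Epoch cap (default 5000); 0 returns the untrained
#'   network with its initial MSE recorded.
#' @param seed Integer seed for weight initialisation.
#' @return Object of class `backprop_mlp` with weight matrices `W1`, `W2`,
#'   `epochs`, `mse`, `converged`.
#' @export
train_backprop <- function(X, y, hidden = 10L, lr = 0.2,
                           target_mse = 0.002, max_epochs = 5000L,
                           seed = NULL) {
  X <- as.matrix(X)
  if (hidden < 1) stop_invalid("hidden must be >= 1")
  if (!all(y %in% c(-1, 1)))
    stop_invalid("labels must be exactly {-1, +1}")
  Tm <- cbind(pvc = as.numeric(y == -1), other = as.numeric(y == 1))
  Xb <- cbind(1, X)

  with_seed(seed, {
    W1 <- matrix(stats::runif((ncol(X) + 1L) * hidden, -0.5, 0.5),
                 ncol(X) + 1L, hidden)
    W2 <- matrix(stats::runif((hidden + 1L) * 2L, -0.5, 0.5),
                 hidden + 1L, 2L)
    mse <- Inf
    epoch <- 0L
    repeat {
      H <- stats::plogis(Xb %*% W1)
      Hb <- cbind(1, H)
      O <- stats::plogis(Hb %*% W2)
      E <- O - Tm
      mse <- mean(E^2)
      if (mse <= target_mse || epoch >= max_epochs) break
      dA2 <- 2 * E * O * (1 - O) / length(E)
      G2 <- crossprod(Hb, dA2)
      dH <- dA2 %*% t(W2[-1L, , drop = FALSE])
      dA1 <- dH * H * (1 - H)
      G1 <- crossprod(Xb, dA1)
      W2 <- W2 - lr * G2
      W1 <- W1 - lr * G1
      epoch <- epoch + 1L
    }
    structure(list(W1 = W1, W2 = W2, hidden = hidden, lr = lr,
                   target_mse = target_mse, epochs = epoch, mse = mse,
                   converged = mse <= target_mse),
              class = "backprop_mlp")
  })
}

#' Predict with the back-propagation network
#'
#' @param object A [train_backprop()] fit.
#' @param X Feature matrix.
#' @param type `"class"` (labels in `{-1, +1}` by the larger output node)
#'   or `"prob"` (the two raw output activations).
#' @param ... Unused.
#' @export
predict.backprop_mlp <- function(object, X, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(X)
  if (ncol(X) != nrow(object$W1) - 1L)
    stop_invalid("feature matrix has %d columns; network expects %d",
                 ncol(X), nrow(object$W1) - 1L)
  H <- stats::plogis(cbind(1, X) %*% object$W1)
  O <- stats::plogis(cbind(1, H) %*% object$W2)
  if (type == "prob") return(O)
  ifelse(O[, 2] >= O[, 1], 1, -1)
}

#' Synthetic labelled beat pool for the classifier benchmark
#'
#' Draws beat feature vectors from documented class-conditional normal
#' distributions that mimic the [extract_features()] geometry (PVC: wide
#' QRS, no P, premature RR with compensatory pause, discordant T). The
#' default composition matches the benchmark design: 1242 beats of which
#' 254 are PVCs, 854 normal and 134 other arrhythmic beats. A small
#' `flip_prob` emulates delineation error: each beat's P detection flips
#' with that probability, and the P-duration and PR features follow the
#' (possibly wrong) detection — a missed P yields zeros on a normal beat, a
#' spurious P yields plausible small values on a PVC — so the classes are
#' not perfectly separable. This pool is a synthetic stand-in for an
#' annotated clinical beat archive.
#'
#' @param n_pvc,n_normal,n_other Class counts.
#' @param flip_prob P-detection flip probability (default 0.08).
#' @param corrupt_prob Fraction of beats with grossly corrupted morphology
#'   features (default 0.1).
#' @param seed Integer seed.
#' @return List of class `beat_pool`: `X` (features), `y` (`-1` PVC /
#'   `+1` other), `class` (character).
#' @export
make_beat_pool <- function(n_pvc = 254L, n_normal = 854L, n_other = 134L,
                           flip_prob = 0.08, corrupt_prob = 0.1,
                           seed = NULL) {
  feat <- c("prev_rr_ratio", "next_rr_ratio", "qrs_ms", "r_amp", "s_depth",
            "p_flag", "p_ms", "pr_ms", "qrs_area", "t_amp")
  mu <- rbind(
    NORMAL = c(1.00, 1.00,  95, 1.15, 0.25, NA, 110, 115,  95,  0.30),
    PVC    = c(0.85, 1.12, 130, 1.30, 0.45, NA,   0,   0, 135, -0.10),
    OTHER  = c(0.92, 1.03, 100, 1.00, 0.22, NA,  95, 100,  95,  0.25))
  sd <- rbind(
    NORMAL = c(0.10, 0.10, 20, 0.25, 0.12, NA, 10, 12, 20, 0.15),
    PVC    = c(0.12, 0.12, 28, 0.30, 0.20, NA,  0,  0, 32, 0.30),
    OTHER  = c(0.10, 0.10, 20, 0.25, 0.12, NA, 12, 12, 20, 0.15))
  colnames(mu) <- colnames(sd) <- feat
  morph <- c("qrs_ms", "r_amp", "s_depth", "qrs_area", "t_amp")

  with_seed(seed, {
    classes <- rep(c("NORMAL", "PVC", "OTHER"), c(n_normal, n_pvc, n_other))
    n <- length(classes)
    X <- matrix(0, n, length(feat), dimnames = list(NULL, feat))
    for (cl in unique(classes)) {
      idx <- which(classes == cl)
      for (f in feat) {
        if (f %in% c("p_flag", "p_ms", "pr_ms")) next
        X[idx, f] <- stats::rnorm(length(idx), mu[cl, f], max(sd[cl, f], 0))
      }
      p_here <- as.numeric(cl != "PVC")
      detected <- stats::rbinom(length(idx), 1, abs(p_here - flip_prob))
      X[idx, "p_flag"] <- detected
      # duration/PR features follow the (noisy) detection, not the truth:
      # spurious detections on PVCs read as short P waves
      p_mu <- if (cl == "PVC") c(p_ms = 60, pr_ms = 80)
              else c(p_ms = mu[cl, "p_ms"], pr_ms = mu[cl, "pr_ms"])
      p_sd <- if (cl == "PVC") c(p_ms = 20, pr_ms = 25)
              else c(p_ms = sd[cl, "p_ms"], pr_ms = sd[cl, "pr_ms"])
      for (f in c("p_ms", "pr_ms"))
        X[idx, f] <- detected *
          pmax(stats::rnorm(length(idx), p_mu[[f]], p_sd[[f]]), 0)
    }
    # a fraction of beats suffers gross delineation failure: their
    # morphology features pick up class-agnostic wide noise
    bad <- which(stats::runif(n) < corrupt_prob)
    for (f in morph) {
      pooled_sd <- 2 * mean(sd[, f])
      X[bad, f] <- X[bad, f] + stats::rnorm(length(bad), 0, pooled_sd)
    }
    structure(list(X = X, y = ifelse(classes == "PVC", -1, 1),
                   class = classes), class = "beat_pool")
  })
}

#' Train/test exchange benchmark of both classifiers
#'
#' Splits the pool into two halves (default 621/621 with 124 PVCs in the
#' training half), trains Gentle AdaBoost and the back-propagation network
#' on the first half, evaluates on the second, then swaps the halves — the
#' exchange experiment — for every seed in `seeds`. Reports per-run overall
#' and per-class accuracy and the median accuracy difference.
#'
#' @param pool A [make_beat_pool()] pool (or compatible list with `X`, `y`).
#' @param n_train Training-half size (default 621).
#' @param train_pvc Number of PVC beats in the training half (default 124).
#' @param seeds Integer seeds, one benchmark repetition each.
#' @param n_iter Boosting rounds (default 100).
#' @param hidden,lr,target_mse,max_epochs Back-propagation settings.
#' @return Object of class `benchmark_report`: `runs` (data.frame) and
#'   `summary` (median test accuracies and their difference,
#'   Gentle AdaBoost minus back-propagation).
#' @export
run_benchmark <- function(pool, n_train = 621L, train_pvc = 124L,
                          seeds = 0:9, n_iter = 100L, hidden = 10L,
                          lr = 0.2, target_mse = 0.002,
                          max_epochs = 2000L) {
  m <- nrow(pool$X)
  n_pvc_pool <- sum(pool$y == -1)
  if (2L * n_train > m)
    stop_invalid("split of 2 x %d exceeds pool size %d", n_train, m)
  if (train_pvc > n_pvc_pool || train_pvc > n_train)
    stop_invalid("train_pvc = %d infeasible (pool has %d PVCs)",
                 train_pvc, n_pvc_pool)

  runs <- list()
  for (sd_i in seeds) {
    split <- with_seed(sd_i, {
      pvc_idx <- which(pool$y == -1)
      oth_idx <- which(pool$y == 1)
      a <- c(sample(pvc_idx, train_pvc),
             sample(oth_idx, n_train - train_pvc))
      list(a = sort(a), b = sort(setdiff(seq_len(m), a))[seq_len(n_train)])
    })
    halves <- list(`A->B` = c("a", "b"), `B->A` = c("b", "a"))
    for (dir_name in names(halves)) {
      tr <- split[[halves[[dir_name]][1]]]
      te <- split[[halves[[dir_name]][2]]]
      gb <- train_gentle_adaboost(pool$X[tr, ], pool$y[tr], n_iter = n_iter)
      bp <- train_backprop(pool$X[tr, ], pool$y[tr], hidden = hidden,
                           lr = lr, target_mse = target_mse,
                           max_epochs = max_epochs,
                           seed = sd_i * 1000L + match(dir_name, names(halves)))
      for (model in c("gentleboost", "backprop")) {
        pred <- if (model == "gentleboost") predict(gb, pool$X[te, ])
                else predict(bp, pool$X[te, ])
        truth <- pool$y[te]
        runs[[length(runs) + 1L]] <- data.frame(
          seed = sd_i, model = model, direction = dir_name,
          accuracy = mean(pred == truth),
          acc_pvc = mean(pred[truth == -1] == -1),
          acc_nonpvc = mean(pred[truth == 1] == 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  runs <- do.call(rbind, runs)
  med <- function(mod) stats::median(runs$accuracy[runs$model == mod])
  structure(list(
    runs = runs,
    summary = list(median_gentleboost = med("gentleboost"),
                   median_backprop = med("backprop"),
                   margin = med("gentleboost") - med("backprop"))),
    class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf(
    "<benchmark_report> median test accuracy: Gentle AdaBoost %.3f, back-propagation %.3f (margin %.3f)\n",
    x$summary$median_gentleboost, x$summary$median_backprop,
    x$summary$margin))
  invisible(x)
}
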