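# Clinical statistics layer: cohort summaries, group tests, from-scratch
# binary logistic regression, ROC/Youden analysis and diagnostic metrics.

#' Per-group cohort summary
#'
#' Counts and percentages for binary covariates (percentage = 100 x count /
#' group size, half-up rounded to one decimal, matching printed clinical
#' tables) and mean +/- SD for continuous variables, per group.
#'
#' @param table A cohort data.frame with a `group` column.
#' @param group_col Name of the grouping column (default `"group"`).
#' @return List of class `cohort_summary`, one element per group, each with
#'   `n`, `binary` (data.frame variable/count/pct) and `continuous`
#'   (data.frame variable/mean/sd).
#' @export
summarize_cohort <- function(table, group_col = "group") {
  if (!nrow(table)) stop_invalid("cohort table is empty")
  if (!group_col %in% names(table))
    stop_invalid("no '%s' column in cohort table", group_col)
  groups <- unique(as.character(table[[group_col]]))
  vars <- setdiff(names(table), c("id", group_col))
  num <- vars[vapply(table[vars], is.numeric, logical(1))]
  is_bin <- vapply(num, function(v) all(table[[v]] %in% c(0, 1)), logical(1))

  out <- lapply(groups, function(g) {
    sub <- table[table[[group_col]] == g, , drop = FALSE]
    if (!nrow(sub)) stop_invalid("group '%s' is empty", g)
    bin <- num[is_bin]
    cont <- num[!is_bin]
    list(n = nrow(sub),
         binary = data.frame(
           variable = bin,
           count = vapply(bin, function(v) sum(sub[[v]]), numeric(1)),
           pct = vapply(bin, function(v)
             round_half_up(100 * sum(sub[[v]]) / nrow(sub), 1), numeric(1)),
           row.names = NULL, stringsAsFactors = FALSE),
         continuous = data.frame(
           variable = cont,
           mean = vapply(cont, function(v) mean(sub[[v]]), numeric(1)),
           sd = vapply(cont, function(v) stats::sd(sub[[v]]), numeric(1)),
           row.names = NULL, stringsAsFactors = FALSE))
  })
  names(out) <- groups
  structure(out, class = "cohort_summary")
}

#' Two-sample t test (pooled or Welch)
#'
#' Accepts either raw value vectors or summary statistics
#' (`list(mean=, sd=, n=)`), since published tables often provide only the
#' latter. Raw vectors are passed to [stats::t.test()]; summary input uses
#' the closed-form statistic. Two groups with zero variance and equal means
#' return `t = 0, p = 1` by convention.
#'
#' @param a,b Numeric vectors, or lists with `mean`, `sd`, `n`.
#' @param variant `"pooled"` (equal variances) or `"welch"`.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
two_sample_t <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  as_sum <- function(v) {
    if (is.list(v)) list(mean = v$mean, sd = v$sd, n = v$n)
    else list(mean = mean(v), sd = stats::sd(v), n = length(v))
  }
  sa <- as_sum(a); sb <- as_sum(b)
  if (sa$n < 2 || sb$n < 2) stop_invalid("each group needs n >= 2")
  if (sa$sd == 0 && sb$sd == 0) {
    if (sa$mean == sb$mean)
      return(list(t = 0, df = sa$n + sb$n - 2, p = 1))
    return(list(t = sign(sa$mean - sb$mean) * Inf,
                df = sa$n + sb$n - 2, p = 0))
  }
  if (!is.list(a) && !is.list(b)) {
    tt <- stats::t.test(a, b, var.equal = (variant == "pooled"))
    return(list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value))
  }
  if (variant == "pooled") {
    df <- sa$n + sb$n - 2
    sp2 <- ((sa$n - 1) * sa$sd^2 + (sb$n - 1) * sb$sd^2) / df
    se <- sqrt(sp2 * (1 / sa$n + 1 / sb$n))
  } else {
    va <- sa$sd^2 / sa$n; vb <- sb$sd^2 / sb$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (sa$n - 1) + vb^2 / (sb$n - 1))
  }
  t <- (sa$mean - sb$mean) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test on a 2x2 table
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param continuity Apply the Yates continuity correction.
#' @return List with `chisq`, `df` (1), `p`.
#' @export
chi_square_test <- function(table, continuity = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)))
    stop_invalid("expected a 2x2 count table")
  if (any(table < 0) || sum(table) == 0)
    stop_invalid("counts must be >= 0 with a positive total")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop_invalid("zero marginal total: chi-square undefined")
  ct <- suppressWarnings(stats::chisq.test(table, correct = continuity))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Binary logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood fit of `P(outcome = positive) = plogis(X b)` with
#' standard errors from the inverse observed information, SPSS-style Wald
#' statistics `(B/SE)^2`, odds ratios `exp(B)` and Wald 95% confidence
#' intervals `exp(B +/- 1.96 SE)`. Convergence is declared when the
#' relative log-likelihood change falls below `tol` (default 1e-10) within
#' `max_iter` iterations (step-halving guards each update); complete
#' separation is flagged — never silent — when any covariate coefficient
#' exceeds 15 in magnitude.
#'
#' @param table Data.frame of covariates and the outcome column.
#' @param covariates Character vector of covariate column names.
#' @param outcome Outcome column name (default `"group"`).
#' @param positive Outcome level coded 1 (default `"AF"`).
#' @param max_iter,tol IRLS controls.
#' @return Object of class `logistic_fit`: `coefficients` data.frame
#'   (`term`, `b`, `se`, `wald`, `or`, `ci_lo`, `ci_hi`, `p`), `loglik`,
#'   `iterations`, `converged`, `separation`, `n`.
#' @export
fit_logistic <- function(table, covariates, outcome = "group",
                         positive = "AF", max_iter = 100L, tol = 1e-10) {
  missing_cols <- setdiff(c(covariates, outcome), names(table))
  if (length(missing_cols))
    stop_invalid("columns not in table: %s",
                 paste(missing_cols, collapse = ", "))
  y <- as.numeric(as.character(table[[outcome]]) == positive)
  if (length(unique(y)) < 2)
    stop_invalid("outcome must have both classes")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(table[, covariates, drop = FALSE]))
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n <= ncol(X))
    stop_invalid("need more observations (%d) than parameters (%d)",
                 n, ncol(X))

  loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  b <- numeric(ncol(X))
  ll <- loglik(b)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    p <- stats::plogis(drop(X %*% b))
    v <- pmax(p * (1 - p), 1e-10)
    info <- crossprod(X, X * v)
    score <- crossprod(X, y - p)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    new_b <- b + drop(step)
    new_ll <- loglik(new_b)
    halvings <- 0L
    while (new_ll < ll && halvings < 20L) {   # step-halving for stability
      step <- step / 2
      new_b <- b + drop(step)
      new_ll <- loglik(new_b)
      halvings <- halvings + 1L
    }
    done <- abs(new_ll - ll) < tol * (abs(ll) + tol)
    b <- new_b
    ll <- new_ll
    if (done) { converged <- TRUE; break }
  }
  p <- stats::plogis(drop(X %*% b))
  v <- pmax(p * (1 - p), 1e-10)
  info <- crossprod(X, X * v)
  cov_b <- tryCatch(solve(info), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  se <- sqrt(diag(cov_b))
  separation <- any(abs(b[-1]) > 15)
  wald <- (b / se)^2
  coefs <- data.frame(term = colnames(X), b = unname(b), se = unname(se),
                      wald = unname(wald), or = exp(unname(b)),
                      ci_lo = exp(unname(b - 1.96 * se)),
                      ci_hi = exp(unname(b + 1.96 * se)),
                      p = stats::pchisq(unname(wald), 1, lower.tail = FALSE),
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, loglik = ll, iterations = iter,
                 converged = converged, separation = separation, n = n),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, logLik = %.3f, %s%s\n", x$n, x$loglik,
              if (x$converged) "converged" else "NOT converged",
              if (x$separation) " [separation flagged]" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' ROC curve, AUC and Youden-index cutoff
#'
#' Empirical ROC over every observed threshold (plus infinite sentinels),
#' with the area computed by trapezoidal integration — identical to the
#' Mann-Whitney concordance probability with ties counted one half. The
#' optimal cutoff maximises the Youden index (sensitivity + specificity
#' - 1); ties are broken toward the least extreme threshold (closest to the
#' score median). `direction = "ge"` calls a score at or above the cutoff
#' positive; `"le"` supports markers whose low values predict the outcome
#' (PTFV1-style).
#'
#' @param scores Numeric marker values.
#' @param labels Class labels.
#' @param positive Label of the positive (diseased) class.
#' @param direction `"ge"` or `"le"`.
#' @return Object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `cutoff`, `youden`, `direction`.
#' @export
roc_analysis <- function(scores, labels, positive = "AF",
                         direction = c("ge", "le")) {
  direction <- match.arg(direction)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  y <- as.character(labels) == as.character(positive)
  if (!any(y) || all(y))
    stop_invalid("both classes must be present for ROC analysis")

  s <- if (direction == "ge") scores else -scores
  ths <- c(Inf, sort(unique(s), decreasing = TRUE))
  sens <- vapply(ths, function(t) mean(s[y] >= t), numeric(1))
  spec <- vapply(ths, function(t) mean(s[!y] < t), numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)

  finite <- is.finite(ths)
  j <- sens + spec - 1
  jf <- j[finite]
  best <- which(jf >= max(jf) - 1e-12)
  if (length(best) > 1) {
    cand <- ths[finite][best]
    best <- best[which.min(abs(cand - stats::median(s)))]
  }
  cutoff_internal <- ths[finite][best]
  youden <- jf[best]

  out_ths <- if (direction == "ge") ths else -ths
  structure(list(thresholds = out_ths, sensitivity = sens,
                 specificity = spec, auc = auc,
                 cutoff = if (direction == "ge") cutoff_internal
                          else -cutoff_internal,
                 youden = youden, direction = direction),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  op <- if (x$direction == "ge") ">=" else "<="
  cat(sprintf("<roc_result> AUC = %.3f; Youden cutoff: score %s %g (J = %.3f)\n",
              x$auc, op, x$cutoff, x$youden))
  invisible(x)
}

#' Diagnostic accuracy metrics from a confusion table
#'
#' Sensitivity, specificity, positive and negative predictive value as
#' percentages half-up rounded to one decimal. An empty predicted-positive
#' set leaves PPV undefined and flagged (likewise NPV).
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @return Object of class `confusion_summary`.
#' @export
diagnostic_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop_invalid("counts must be >= 0")
  if (tp + fn == 0 || tn + fp == 0)
    stop_invalid("need at least one actual positive and one actual negative")
  pct <- function(num, den) if (den == 0) NA_real_
         else round_half_up(100 * num / den, 1)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = pct(tp, tp + fn),
                 specificity = pct(tn, tn + fp),
                 ppv = pct(tp, tp + fp), npv = pct(tn, tn + fn),
                 ppv_defined = (tp + fp) > 0,
                 npv_defined = (tn + fn) > 0),
            class = "confusion_summary")
}

#' Full clinical analysis of a two-group cohort
#'
#' Cohort summary, continuous-variable t tests, binary-covariate chi-square
#' tests, multivariate logistic regression, and per-marker ROC analysis
#' with Youden cutoff and diagnostic metrics at that cutoff.
#'
#' @param table A cohort data.frame (see [generate_cohort()]).
#' @param markers Named character vector mapping marker columns to ROC
#'   direction, e.g. `c(pmax = "ge", pmin = "ge", ptfv1 = "le")`.
#' @param covariates Covariates for the logistic model.
#' @param positive Positive group label (default `"AF"`).
#' @param variant t-test variant.
#' @return List of class `cohort_report` with `summary`, `group_tests`,
#'   `logistic`, `markers` (per marker: `roc`, `cutoff`, `auc`,
#'   `metrics`).
#' @export
cohort_analyze <- function(table,
                           markers = c(pmax = "ge", pmin = "ge",
                                       ptfv1 = "le"),
                           covariates = c("male", "pmax", "pmin", "ptfv1",
                                          "lad"),
                           positive = "AF",
                           variant = "pooled") {
  covariates <- intersect(covariates, names(table))
  groups <- unique(as.character(table$group))
  if (length(groups) != 2) stop_invalid("cohort must have exactly 2 groups")
  g_pos <- positive
  g_neg <- setdiff(groups, positive)

  summ <- summarize_cohort(table)
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  num <- setdiff(num, "id")
  bin <- num[vapply(num, function(v) all(table[[v]] %in% c(0, 1)), logical(1))]
  cont <- setdiff(num, bin)

  tests <- list()
  for (v in cont) {
    tt <- two_sample_t(table[[v]][table$group == g_pos],
                       table[[v]][table$group == g_neg], variant = variant)
    tests[[v]] <- c(type = "t", stat = tt$t, df = tt$df, p = tt$p)
  }
  for (v in bin) {
    tab <- base::table(factor(table$group, levels = c(g_pos, g_neg)),
                       factor(table[[v]], levels = c(1, 0)))
    ct <- chi_square_test(tab)
    tests[[v]] <- c(type = "chisq", stat = ct$chisq, df = ct$df, p = ct$p)
  }

  logit <- fit_logistic(table, covariates, positive = positive)

  mk <- lapply(names(markers), function(v) {
    roc <- roc_analysis(table[[v]], table$group, positive = positive,
                        direction = markers[[v]])
    pos_call <- if (markers[[v]] == "ge") table[[v]] >= roc$cutoff
                else table[[v]] <= roc$cutoff
    truth <- table$group == positive
    metrics <- diagnostic_metrics(tp = sum(pos_call & truth),
                                  fp = sum(pos_call & !truth),
                                  tn = sum(!pos_call & !truth),
                                  fn = sum(!pos_call & truth))
    list(marker = v, direction = markers[[v]], auc = roc$auc,
         cutoff = roc$cutoff, youden = roc$youden, roc = roc,
         metrics = metrics)
  })
  names(mk) <- names(markers)

  structure(list(summary = summ, group_tests = tests, logistic = logit,
                 markers = mk, positive = positive),
            class = "cohort_report")
}
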