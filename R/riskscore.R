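#' Compute the pair-signature risk score
#'
#' `Riskscore = sum_k coef_k * indicator_k` over the signature pairs, where
#' each indicator is the 0/1 pair value of the sample. Because the
#' indicators are rank-based, the score is invariant to strictly increasing
#' per-sample transforms of the underlying expression.
#'
#' @param model a `signature_model`.
#' @param pm a `pair_matrix` containing every signature pair column (e.g.
#'   from [build_pair_matrix()] or [pair_indicators()]).
#' @return named numeric vector of scores, one per sample.
#' @export
compute_riskscore <- function(model, pm) {
  stopifnot(inherits(model, "signature_model"), inherits(pm, "pair_matrix"))
  want <- names(model$coefficients)
  missing <- setdiff(want, colnames(pm$values))
  if (length(missing))
    stop("pair matrix lacks signature pair(s): ",
         paste(missing, collapse = ", "))
  drop(pm$values[, want, drop = FALSE] %*% model$coefficients)
}

# Product-limit survival probability at one horizon (right-continuous,
# events at the horizon included). Direct evaluation: the ROC scan calls
# this for two subgroups per operating point.
km_surv_at <- function(time, event, horizon) {
  n <- length(time)
  if (n == 0) return(1)
  o <- order(time)
  t_s <- time[o]
  e_s <- event[o]
  idx <- e_s == 1 & t_s <= horizon
  if (!any(idx)) return(1)
  ut <- unique(t_s[idx])
  d <- tabulate(match(t_s[idx], ut))
  nrisk <- n - findInterval(ut, t_s, left.open = TRUE)
  prod(1 - d / nrisk)
}

#' Time-dependent ROC curve (cumulative/dynamic, KM-adjusted)
#'
#' Cases are subjects with an observed event by the horizon, controls those
#' still at risk beyond it; censoring before the horizon is handled with
#' the Kaplan-Meier-based estimator: for a threshold `c`,
#' `Sens(c) = (1 - S(h | X > c)) P(X > c) / (1 - S(h))` and
#' `Spec(c) = S(h | X <= c) P(X <= c) / S(h)`, where `S` is the subgroup
#' Kaplan-Meier survival at the horizon `h`. Thresholds are the midpoints
#' of the sorted unique scores; values are clipped to `[0, 1]` and the
#' curve is anchored at (0,0) and (1,1). The AUC is the trapezoidal area
#' over `(1 - specificity, sensitivity)`. With no censoring before the
#' horizon this reduces exactly to the empirical case/control concordance.
#'
#' @param score numeric risk score per sample.
#' @param time,event survival outcome per sample.
#' @param horizon evaluation time in days, within the observed follow-up.
#' @return An object of class `roc_curve`: list with `horizon`,
#'   `thresholds`, `sensitivity`, `specificity`, `auc`.
#' @export
time_dependent_roc <- function(score, time, event, horizon) {
  n <- length(score)
  stopifnot(length(time) == n, length(event) == n)
  if (horizon <= 0 || horizon > max(time))
    stop("`horizon` must lie within the observed follow-up")
  s_h <- km_surv_at(time, event, horizon)
  if (s_h <= 0 || s_h >= 1)
    stop("degenerate horizon: overall survival at the horizon is ",
         signif(s_h, 3))
  us <- sort(unique(score))
  if (length(us) < 2) stop("at least 2 distinct scores are required")
  mids <- (us[-1] + us[-length(us)]) / 2
  sens <- spec <- numeric(length(mids))
  for (i in seq_along(mids)) {
    hi <- score > mids[i]
    p_hi <- mean(hi)
    s_hi <- km_surv_at(time[hi], event[hi], horizon)
    s_lo <- km_surv_at(time[!hi], event[!hi], horizon)
    sens[i] <- (1 - s_hi) * p_hi / (1 - s_h)
    spec[i] <- s_lo * (1 - p_hi) / s_h
  }
  sens <- pmin(pmax(sens, 0), 1)
  spec <- pmin(pmax(spec, 0), 1)
  thresholds <- c(-Inf, mids, Inf)
  sens <- c(1, sens, 0)
  spec <- c(0, spec, 1)
  fpr <- 1 - spec
  # traverse the curve from (0,0) to (1,1) in decreasing-threshold order:
  # sorting by coordinates instead would let floating-point noise reorder
  # the vertical segments of the staircase
  ord <- order(thresholds, decreasing = TRUE)
  ts <- sens[ord]
  tf <- fpr[ord]
  auc <- sum(diff(tf) * (ts[-1] + ts[-length(ts)]) / 2)
  structure(list(horizon = horizon, thresholds = thresholds,
                 sensitivity = sens, specificity = spec, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("Time-dependent ROC at ", x$horizon, " days: AUC = ",
      round(x$auc, 3), " (", length(x$thresholds) - 2,
      " operating points)\n", sep = "")
  invisible(x)
}

#' AIC-optimal dichotomising cutoff on the 1-year ROC operating points
#'
#' Scans the operating points of the 1-year time-dependent ROC curve (the
#' midpoints of the sorted unique scores), keeping candidates for which
#' both resulting groups contain at least `min_group_frac` of the cohort,
#' and fits a single-covariate Cox model on `I(score > c)` for each. The
#' cutoff with minimal `AIC = -2 logPL + 2` is returned (ties broken toward
#' the smaller cutoff). `method = "youden"` instead maximises
#' `sensitivity + specificity - 1` on the same curve.
#'
#' @param score numeric risk score per sample (>= 2 distinct values).
#' @param time,event survival outcome per sample.
#' @param horizon ROC horizon in days; default 365 (1 year).
#' @param min_group_frac minimum fraction of the cohort per group; guards
#'   against degenerate extreme splits.
#' @param method `"aic"` (default) or `"youden"`.
#' @return list of class `cutoff_search`: `cutoff`, `trace` (data.frame of
#'   candidate cutoffs with criterion values and group sizes), `method`,
#'   `horizon`.
#' @export
aic_optimal_cutoff <- function(score, time, event, horizon = 365,
                               min_group_frac = 0.1,
                               method = c("aic", "youden")) {
  method <- match.arg(method)
  n <- length(score)
  us <- sort(unique(score))
  if (length(us) < 2) stop("at least 2 distinct scores are required")
  mids <- (us[-1] + us[-length(us)]) / 2
  n_high <- vapply(mids, function(c) sum(score > c), numeric(1))
  admissible <- pmin(n_high, n - n_high) >= min_group_frac * n
  if (!any(admissible))
    stop("no candidate cutoff leaves both groups with >= ",
         min_group_frac * 100, "% of the cohort; lower `min_group_frac`")
  mids <- mids[admissible]
  n_high <- n_high[admissible]
  if (method == "aic") {
    df <- data.frame(.time = time, .event = event, high = 0)
    crit <- vapply(mids, function(c) {
      df$high <- as.numeric(score > c)
      f <- tryCatch(suppressWarnings(
        survival::coxph(survival::Surv(.time, .event) ~ high, data = df,
                        ties = "efron")),
        error = function(e) NULL)
      if (is.null(f) || is.na(f$coefficients)) Inf else
        -2 * f$loglik[2] + 2
    }, numeric(1))
    best <- which(crit == min(crit))[1]  # ties: smaller cutoff
  } else {
    roc <- time_dependent_roc(score, time, event, horizon)
    idx <- match(mids, roc$thresholds)
    crit <- -(roc$sensitivity[idx] + roc$specificity[idx] - 1)
    best <- which(crit == min(crit))[1]
  }
  trace <- data.frame(cutoff = mids, criterion = crit,
                      n_high = n_high, n_low = n - n_high)
  structure(list(cutoff = mids[best], trace = trace, method = method,
                 horizon = horizon, min_group_frac = min_group_frac),
            class = "cutoff_search")
}

#' @export
print.cutoff_search <- function(x, ...) {
  at <- x$trace[x$trace$cutoff == x$cutoff, ]
  cat("Optimal cutoff (", x$method, "): ", signif(x$cutoff, 4),
    " -> high n = ", at$n_high, ", low n = ", at$n_low, "\n", sep = "")
  invisible(x)
}

#' Stratify samples into high and low risk
#'
#' `high` iff `score > cutoff` (strict); scores equal to the cutoff fall in
#' the low-risk group.
#'
#' @param score numeric risk score per sample.
#' @param cutoff finite numeric cutoff.
#' @return factor with levels `low`, `high`, named like `score`.
#' @export
stratify <- function(score, cutoff) {
  if (!is.finite(cutoff)) stop("`cutoff` must be finite")
  f <- factor(ifelse(score > cutoff, "high", "low"),
              levels = c("low", "high"))
  names(f) <- names(score)
  f
}
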