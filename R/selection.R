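#' Fit a Cox proportional hazards model
#'
#' Wrapper around [survival::coxph()] (partial-likelihood Newton-Raphson,
#' Efron or Breslow tie handling) that validates the design matrix up front
#' and returns a compact, serialisable fit summary. Constant columns are
#' rejected as unidentifiable; rank-deficient designs raise a collinearity
#' error naming the offending columns; monotone-likelihood (perfect
#' separation) warnings are caught and flagged on the result.
#'
#' @param x numeric covariate matrix, samples x covariates, with column
#'   names.
#' @param time,event follow-up time (days, positive) and event indicator
#'   (0/1) per sample; at least one event.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return An object of class `cox_fit`: list with `coefficients`, `se`,
#'   `hr`, `ci95` (matrix with columns `lo`, `hi`), `wald_p`,
#'   `log_partial_likelihood`, `aic` (`-2 logPL + 2k`), `n`, `n_events`,
#'   `monotone` flag and the underlying `coxph` object in `$object`.
#' @examples
#' set.seed(1)
#' x <- cbind(marker = rbinom(60, 1, 0.5))
#' tt <- rexp(60, 0.01 * exp(0.8 * x[, 1]))
#' fit_cox(x, tt, rep(1, 60))
#' @export
fit_cox <- function(x, time, event, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (length(time) != nrow(x) || length(event) != nrow(x))
    stop("`time` and `event` must match the rows of `x`")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be positive and finite")
  if (sum(event) < 1) stop("at least one event is required")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant covariate(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  qr_x <- qr(scale(x, center = TRUE, scale = FALSE))
  if (qr_x$rank < ncol(x)) {
    dep <- colnames(x)[sort(qr_x$pivot[-seq_len(qr_x$rank)])]
    stop("collinear covariate(s): ", paste(dep, collapse = ", "))
  }
  df <- as.data.frame(x)
  names(df) <- paste0("V", seq_len(ncol(x)))
  df$.time <- time
  df$.event <- event
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ . - .time - .event,
                    data = df, ties = ties,
                    control = survival::coxph.control(iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|converged before", conditionMessage(w)))
        monotone <<- TRUE
      invokeRestart("muffleWarning")
    })
  b <- unname(fit$coefficients)
  if (anyNA(b))
    stop("collinear covariate(s): ",
         paste(colnames(x)[is.na(fit$coefficients)], collapse = ", "))
  se <- sqrt(diag(as.matrix(fit$var)))
  k <- length(b)
  logpl <- fit$loglik[2]
  structure(list(
    coefficients = stats::setNames(b, colnames(x)),
    se = stats::setNames(se, colnames(x)),
    hr = stats::setNames(exp(b), colnames(x)),
    ci95 = matrix(exp(c(b - 1.96 * se, b + 1.96 * se)), ncol = 2,
                  dimnames = list(colnames(x), c("lo", "hi"))),
    wald_p = stats::setNames(2 * stats::pnorm(-abs(b / se)), colnames(x)),
    log_partial_likelihood = logpl,
    aic = -2 * logpl + 2 * k,
    n = fit$n, n_events = fit$nevent,
    monotone = monotone, ties = ties, object = fit),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat("Cox model (", x$ties, " ties): n = ", x$n, ", events = ",
      x$n_events, ", AIC = ", round(x$aic, 2), "\n", sep = "")
  tab <- data.frame(coef = x$coefficients, HR = x$hr,
                    lo95 = x$ci95[, "lo"], hi95 = x$ci95[, "hi"],
                    p = x$wald_p)
  print(round(tab, digits))
  if (x$monotone)
    cat("warning: monotone partial likelihood (possible separation)\n")
  invisible(x)
}

#' Univariate Cox screen of pair indicators
#'
#' Fits one single-covariate Cox model per pair column and keeps pairs with
#' Wald `p < p_max`. No multiplicity correction is applied at this stage
#' (the screen is a pre-filter for the penalised selection that follows);
#' pass `adjust = "bh"` to screen on BH-adjusted p-values instead. Columns
#' that are constant on the analysis samples, or whose fit fails, are
#' dropped with a message.
#'
#' @param pm a `pair_matrix` aligned with `time`/`event` by row.
#' @param time,event survival outcome per sample.
#' @param p_max retention threshold on the (possibly adjusted) Wald p.
#' @param adjust `"none"` (default, mirrors raw p < 0.05 screening) or
#'   `"bh"`.
#' @return list of class `univariate_screen`: `table` (data.frame `pair`,
#'   `coef`, `hr`, `lo95`, `hi95`, `p`, `p_screen`, `kept`), `kept`
#'   (character vector of retained pair names) and `dropped` (unfittable
#'   columns).
#' @export
univariate_screen <- function(pm, time, event, p_max = 0.05,
                              adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(pm, "pair_matrix"))
  x <- pm$values
  if (nrow(x) != length(time))
    stop("pair matrix and survival data must cover the same samples")
  df <- data.frame(.time = time, .event = event, v = 0)
  res <- vector("list", ncol(x))
  for (j in seq_len(ncol(x))) {
    if (stats::sd(x[, j]) == 0) next  # constant after subsetting
    df$v <- x[, j]
    fit <- tryCatch(suppressWarnings(
      survival::coxph(survival::Surv(.time, .event) ~ v, data = df,
                      ties = "efron")),
      error = function(e) NULL)
    if (is.null(fit) || is.na(fit$coefficients)) next
    b <- unname(fit$coefficients)
    se <- sqrt(fit$var[1, 1])
    res[[j]] <- c(coef = b, hr = exp(b),
                  lo95 = exp(b - 1.96 * se), hi95 = exp(b + 1.96 * se),
                  p = 2 * stats::pnorm(-abs(b / se)))
  }
  ok <- !vapply(res, is.null, logical(1))
  dropped <- colnames(x)[!ok]
  if (length(dropped))
    message(length(dropped),
            " pair(s) dropped from univariate screen (degenerate fits)")
  tab <- as.data.frame(do.call(rbind, res[ok]))
  tab <- cbind(pair = colnames(x)[ok], tab, stringsAsFactors = FALSE)
  tab$p_screen <- if (adjust == "bh") benjamini_hochberg(tab$p) else tab$p
  tab$kept <- tab$p_screen < p_max
  rownames(tab) <- NULL
  structure(list(table = tab, kept = tab$pair[tab$kept], dropped = dropped,
                 p_max = p_max, adjust = adjust),
            class = "univariate_screen")
}

#' @export
print.univariate_screen <- function(x, ...) {
  cat("Univariate Cox screen:", nrow(x$table), "pairs tested,",
      length(x$kept), "kept at p <", x$p_max,
      if (x$adjust == "bh") "(BH adjusted)" else "(unadjusted)", "\n")
  invisible(x)
}

#' Repeated cross-validated Lasso-Cox frequency selection
#'
#' Runs `n_reps` independent repetitions of 10-fold cross-validated
#' L1-penalised Cox regression ([glmnet::cv.glmnet()], partial-likelihood
#' deviance loss, 100 log-spaced penalties from the null-model penalty down
#' to 0.01 of it). Each repetition draws a fresh fold assignment from its
#' own seed (spawned from `seed`), picks the deviance-minimising penalty
#' (`lambda_rule = "min"`, or the one-standard-error rule with `"1se"`) and
#' records which pairs have nonzero coefficients there. A pair is selected
#' when its frequency over repetitions exceeds `freq_min`.
#'
#' @param x numeric matrix of screened pair indicators, samples x pairs
#'   (>= 2 columns).
#' @param time,event survival outcome per sample.
#' @param n_reps number of repetitions (the reference analysis uses 1000).
#' @param n_folds folds per repetition; must not exceed the sample count.
#' @param freq_min strict frequency threshold (reference analysis: 100 of
#'   1000).
#' @param seed master seed for the fold streams.
#' @param lambda_rule `"min"` (default) or `"1se"`.
#' @param thresh coordinate-descent convergence tolerance for the penalised
#'   path fits. The default (1e-5) is looser than for a one-off fit: the
#'   repetitions only vote on which pairs are selected, and the final
#'   coefficients are refit exactly by [stepwise_cox()].
#' @return list of class `lasso_selection`: `frequency` (named counts),
#'   `selected` (named logical), `lambda_trace`, `n_reps`, `freq_min`,
#'   `seed`, `n_failed`.
#' @export
lasso_frequency_select <- function(x, time, event, n_reps = 1000L,
                                   n_folds = 10L, freq_min = 100L,
                                   seed = 1L,
                                   lambda_rule = c("min", "1se"),
                                   thresh = 1e-5) {
  lambda_rule <- match.arg(lambda_rule)
  if (!is.matrix(x) || ncol(x) < 2)
    stop("at least 2 screened pairs are required for the Lasso step")
  n <- nrow(x)
  if (n_folds > n) stop("`n_folds` must not exceed the number of samples")
  if (freq_min >= n_reps)
    warning("`freq_min` >= `n_reps`: only pairs chosen in every repetition ",
            "can survive")
  storage.mode(x) <- "double"
  y <- survival::Surv(time, event)
  # penalty grid: 100 log-spaced values from the smallest penalty nulling
  # every coefficient down to 0.01 of it, fixed across repetitions
  path <- glmnet::glmnet(x, y, family = "cox", alpha = 1,
                         nlambda = 100, lambda.min.ratio = 0.01,
                         thresh = thresh)
  lambda_max <- max(path$lambda)
  lambda <- exp(seq(log(lambda_max), log(0.01 * lambda_max), length.out = 100))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  freq <- stats::setNames(integer(ncol(x)), colnames(x))
  lambda_trace <- rep(NA_real_, n_reps)
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    foldid <- sample(rep(seq_len(n_folds), length.out = n))
    cv <- tryCatch(
      glmnet::cv.glmnet(x, y, family = "cox", alpha = 1, foldid = foldid,
                        lambda = lambda, thresh = thresh),
      error = function(e) NULL)
    if (is.null(cv)) {
      n_failed <- n_failed + 1L
      next
    }
    lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
    lambda_trace[r] <- lam
    nz <- which(as.numeric(stats::coef(cv, s = lam)) != 0)
    freq[nz] <- freq[nz] + 1L
  }
  if (n_failed > 0)
    warning(n_failed, " of ", n_reps, " repetitions failed and were skipped")
  if (all(freq == 0))
    warning("no pair was ever selected by the penalised Cox path")
  structure(list(frequency = freq, selected = freq > freq_min,
                 lambda_trace = lambda_trace, n_reps = n_reps,
                 n_folds = n_folds, freq_min = freq_min, seed = seed,
                 lambda_rule = lambda_rule, n_failed = n_failed),
            class = "lasso_selection")
}

#' @export
print.lasso_selection <- function(x, ...) {
  cat("Lasso-Cox frequency selection:", x$n_reps, "repetitions of",
      x$n_folds, "fold CV;", sum(x$selected), "of", length(x$frequency),
      "pairs with frequency >", x$freq_min, "\n")
  invisible(x)
}

#' Backward-AIC stepwise multivariate Cox model
#'
#' Starting from the multivariate Cox model on all selected pairs,
#' repeatedly removes the covariate whose removal most decreases the AIC
#' (`-2 logPL + 2k`), stopping when no removal decreases it (the empty
#' model counts as a removal candidate for a one-covariate model). Exactly
#' collinear columns are pruned beforehand, keeping the first in canonical
#' column order. The surviving covariates and their multivariate
#' coefficients form the signature.
#'
#' @param x numeric matrix of selected pair indicators, samples x pairs
#'   (>= 1 column).
#' @param time,event survival outcome per sample.
#' @param provenance optional list of upstream thresholds/seeds stored on
#'   the model.
#' @return An object of class `signature_model`: list with `pairs`
#'   (data.frame `lnc_a`, `lnc_b`), `coefficients` (named by `"A|B"`),
#'   `fit` (the final multivariate `cox_fit`) and `provenance`.
#' @export
stepwise_cox <- function(x, time, event, provenance = list()) {
  if (!is.matrix(x) || ncol(x) < 1)
    stop("at least 1 selected pair is required for the stepwise model")
  # prune exact collinearity, keeping the earliest column
  keep <- seq_len(ncol(x))
  qr_x <- qr(scale(x, center = TRUE, scale = FALSE))
  if (qr_x$rank < ncol(x)) {
    drop_idx <- sort(qr_x$pivot[-seq_len(qr_x$rank)])
    warning("collinear pair column(s) pruned before stepwise: ",
            paste(colnames(x)[drop_idx], collapse = ", "))
    keep <- setdiff(keep, drop_idx)
  }
  current <- colnames(x)[keep]
  null_ll <- null_cox_loglik(time, event)
  aic_of <- function(cols) {
    if (length(cols) == 0) return(-2 * null_ll)
    f <- tryCatch(fit_cox(x[, cols, drop = FALSE], time, event),
                  error = function(e) NULL)
    if (is.null(f)) Inf else f$aic
  }
  aic_now <- aic_of(current)
  if (!is.finite(aic_now)) {  # full model unfittable: shed columns until it is
    while (!is.finite(aic_now) && length(current) > 1) {
      warning("dropping `", current[length(current)],
              "`: multivariate fit failed")
      current <- current[-length(current)]
      aic_now <- aic_of(current)
    }
  }
  repeat {
    if (length(current) == 0) break
    cand_aic <- vapply(seq_along(current),
                       function(j) aic_of(current[-j]), numeric(1))
    best <- which.min(cand_aic)  # ties: earliest (canonical) removal
    if (cand_aic[best] < aic_now) {
      current <- current[-best]
      aic_now <- cand_aic[best]
    } else break
  }
  if (length(current) == 0) {
    warning("stepwise elimination removed every pair; empty signature")
    return(structure(list(pairs = data.frame(lnc_a = character(0),
                                             lnc_b = character(0)),
                          coefficients = stats::setNames(numeric(0),
                                                         character(0)),
                          fit = NULL, provenance = provenance),
                     class = "signature_model"))
  }
  fit <- fit_cox(x[, current, drop = FALSE], time, event)
  parts <- do.call(rbind, strsplit(current, "|", fixed = TRUE))
  structure(list(pairs = data.frame(lnc_a = parts[, 1], lnc_b = parts[, 2],
                                    stringsAsFactors = FALSE),
                 coefficients = fit$coefficients,
                 fit = fit, provenance = provenance),
            class = "signature_model")
}

# log partial likelihood of the null (no-covariate) Cox model
null_cox_loglik <- function(time, event) {
  f <- survival::coxph(survival::Surv(time, event) ~ 1)
  f$loglik[1]
}

#' @export
print.signature_model <- function(x, digits = 3, ...) {
  cat("lncRNA pair signature:", nrow(x$pairs), "pairs\n")
  if (nrow(x$pairs)) {
    tab <- data.frame(pair = names(x$coefficients),
                      coef = round(x$coefficients, digits),
                      HR = round(exp(x$coefficients), digits),
                      p = signif(x$fit$wald_p, 3), row.names = NULL)
    print(tab)
  }
  invisible(x)
}

#' @export
coef.signature_model <- function(object, ...) object$coefficients

#' Serialise / restore a signature model as JSON
#'
#' `write_signature()` stores the pairs, coefficients and provenance (plus
#' the hazard ratios and Wald p-values of the final fit) at full double
#' precision; `read_signature()` restores a `signature_model` whose pairs
#' and coefficients round-trip exactly. The underlying `coxph` object is
#' not serialised.
#'
#' @param model a `signature_model`.
#' @param path JSON file path.
#' @return `write_signature()` returns `path` invisibly;
#'   `read_signature()` returns a `signature_model`.
#' @export
write_signature <- function(model, path) {
  stopifnot(inherits(model, "signature_model"))
  payload <- list(pairs = model$pairs,
                  coefficients = as.list(model$coefficients),
                  # hex floats make the round-trip bit-exact
                  coefficients_hex = as.list(stats::setNames(
                    sprintf("%a", model$coefficients),
                    names(model$coefficients))),
                  hr = if (!is.null(model$fit)) as.list(model$fit$hr),
                  wald_p = if (!is.null(model$fit)) as.list(model$fit$wald_p),
                  provenance = model$provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- if (!is.null(payload$coefficients_hex))
    vapply(payload$coefficients_hex, as.numeric, numeric(1)) else
    unlist(payload$coefficients)
  pairs <- as.data.frame(payload$pairs, stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 coefficients = stats::setNames(as.numeric(coefs),
                                                names(coefs)),
                 fit = NULL,
                 provenance = payload$provenance),
            class = "signature_model")
}
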