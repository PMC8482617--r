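#' Kaplan-Meier curves and log-rank comparison by group
#'
#' Product-limit survival estimate per group ([survival::survfit()]) and
#' the log-rank test ([survival::survdiff()]): at each event time the
#' observed minus hypergeometric-expected event counts per group are
#' accumulated and referenced to a chi-square distribution on
#' `(#groups - 1)` degrees of freedom.
#'
#' @param time,event survival outcome per sample.
#' @param groups factor of group labels; every level must be non-empty.
#' @return An object of class `km_result`: `curves` (per-group data.frames
#'   `time`, `surv`, `n_risk`, `n_event`), `median_survival` (named, `NA`
#'   when not reached), `logrank_chi2`, `logrank_df`, `logrank_p`.
#' @export
kaplan_meier <- function(time, event, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2)
    stop("at least 2 non-empty groups are required")
  if (any(table(groups) == 0)) stop("every group must be non-empty")
  df <- data.frame(time = time, event = event, g = groups)
  sf <- survival::survfit(survival::Surv(time, event) ~ g, data = df)
  strata_id <- rep(seq_along(sf$strata), sf$strata)
  curves <- lapply(seq_along(sf$strata), function(i) {
    sel <- strata_id == i
    data.frame(time = sf$time[sel], surv = sf$surv[sel],
               n_risk = sf$n.risk[sel], n_event = sf$n.event[sel])
  })
  names(curves) <- sub("^g=", "", names(sf$strata))
  med <- summary(sf)$table[, "median"]
  names(med) <- sub("^g=", "", rownames(summary(sf)$table))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  df_lr <- nlevels(groups) - 1
  structure(list(curves = curves, median_survival = med,
                 logrank_chi2 = unname(sd_$chisq), logrank_df = df_lr,
                 logrank_p = stats::pchisq(sd_$chisq, df_lr,
                                           lower.tail = FALSE)),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat("Kaplan-Meier comparison of", length(x$curves), "groups\n")
  cat("  median survival:",
      paste(names(x$median_survival),
            ifelse(is.na(x$median_survival), "not reached",
                   round(x$median_survival, 1)),
            sep = " = ", collapse = ", "), "\n")
  cat("  log-rank chi2 =", round(x$logrank_chi2, 3), "on", x$logrank_df,
      "df, p =", signif(x$logrank_p, 3), "\n")
  invisible(x)
}

#' Univariate and multivariate Cox independence analysis
#'
#' Tests whether the risk score carries prognostic information independent
#' of the clinical covariates: one univariate Cox fit per variable (the
#' score entered continuous, ordinal covariates numeric-coded) plus one
#' joint multivariate fit, all via [fit_cox()]. Collinear covariates raise
#' an error naming them.
#'
#' @param score numeric risk score per sample.
#' @param covariates data.frame or matrix of numeric-coded clinical
#'   covariates (e.g. `age`, `grade` 1-3, `stage` 1-4), same samples.
#' @param time,event survival outcome per sample.
#' @return list of class `independence_cox`: `univariate` (named list of
#'   one-covariate `cox_fit`s), `multivariate` (joint `cox_fit`), and
#'   `table` (forest-plot-ready data.frame `variable`, `analysis`, `hr`,
#'   `lo95`, `hi95`, `p`).
#' @export
independence_cox <- function(score, covariates, time, event) {
  cov_m <- as.matrix(as.data.frame(covariates))
  if (!is.numeric(cov_m)) stop("covariates must be numeric-coded")
  x <- cbind(riskscore = as.numeric(score), cov_m)
  uni <- lapply(colnames(x), function(v)
    fit_cox(x[, v, drop = FALSE], time, event))
  names(uni) <- colnames(x)
  multi <- fit_cox(x, time, event)
  row_of <- function(f, v, a) data.frame(
    variable = v, analysis = a, hr = unname(f$hr[v]),
    lo95 = f$ci95[v, "lo"], hi95 = f$ci95[v, "hi"],
    p = unname(f$wald_p[v]), stringsAsFactors = FALSE)
  tab <- rbind(
    do.call(rbind, lapply(names(uni),
                          function(v) row_of(uni[[v]], v, "univariate"))),
    do.call(rbind, lapply(colnames(x),
                          function(v) row_of(multi, v, "multivariate"))))
  rownames(tab) <- NULL
  structure(list(univariate = uni, multivariate = multi, table = tab),
            class = "independence_cox")
}

#' @export
print.independence_cox <- function(x, ...) {
  cat("Cox independence analysis\n")
  tab <- x$table
  tab$hr <- round(tab$hr, 3); tab$lo95 <- round(tab$lo95, 3)
  tab$hi95 <- round(tab$hi95, 3); tab$p <- signif(tab$p, 3)
  print(tab)
  invisible(x)
}
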