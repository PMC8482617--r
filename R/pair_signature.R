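#' Tuning parameters for the pair-signature pipeline
#'
#' Collects every threshold of the pipeline with the reference defaults:
#' differential expression at |log2FC| > 1 and FDR < 0.01; coexpression at
#' |rho| > 0.4 and p <= 0.05; pair validity strictly between 20% and 80%;
#' univariate Cox screen at p < 0.05; 1000 repetitions of 10-fold
#' cross-validated Lasso-Cox with frequency threshold 100; ROC horizons at
#' 1, 2 and 3 years; AIC cutoff search on the 1-year curve with at least
#' 10% of the cohort per group.
#'
#' @param fc_min,fdr_max differential-expression thresholds (log2 scale /
#'   BH-adjusted p).
#' @param de_method `"moderated_t"` or `"welch_t"`.
#' @param pseudocount added before log2 in the DE step.
#' @param rho_min,rho_p_max,rho_signed coexpression-screen thresholds.
#' @param pair_low,pair_high open-interval bounds on the pair one-fraction.
#' @param screen_p_max,screen_adjust univariate Cox screen threshold and
#'   optional BH adjustment (`"none"` or `"bh"`).
#' @param n_reps,n_folds,freq_min,lambda_rule Lasso-Cox selection settings.
#' @param horizons ROC horizons in days.
#' @param cutoff_horizon horizon (days) whose ROC operating points feed the
#'   cutoff search.
#' @param min_group_frac minimum group fraction for admissible cutoffs.
#' @param cutoff_method `"aic"` or `"youden"`.
#' @return A list of class `signature_control`.
#' @export
signature_control <- function(fc_min = 1, fdr_max = 0.01,
                              de_method = "moderated_t", pseudocount = 1,
                              rho_min = 0.4, rho_p_max = 0.05,
                              rho_signed = FALSE,
                              pair_low = 0.2, pair_high = 0.8,
                              screen_p_max = 0.05, screen_adjust = "none",
                              n_reps = 1000L, n_folds = 10L,
                              freq_min = 100L, lambda_rule = "min",
                              horizons = c(365, 730, 1095),
                              cutoff_horizon = 365,
                              min_group_frac = 0.1,
                              cutoff_method = "aic") {
  ctrl <- as.list(environment())
  if (ctrl$pair_low >= ctrl$pair_high)
    stop("`pair_low` must be strictly less than `pair_high`")
  class(ctrl) <- "signature_control"
  ctrl
}

#' Fit a prognostic lncRNA-pair signature
#'
#' End-to-end pipeline from an annotated expression matrix, a clinical
#' table and a stemness-related gene (SRG) list to a fitted risk model:
#'
#' 1. differential expression of lncRNAs, tumor vs normal;
#' 2. Spearman coexpression of lncRNAs with SRGs on tumor samples;
#' 3. candidates = lncRNAs passing both screens;
#' 4. 0/1 pair-indicator matrix over candidates (tumor samples), filtered
#'    to pairs with an informative one-fraction;
#' 5. univariate Cox screen of pairs;
#' 6. repeated cross-validated Lasso-Cox frequency selection;
#' 7. backward-AIC stepwise multivariate Cox -> signature coefficients;
#' 8. risk score, AIC-optimal cutoff on the 1-year ROC, stratification;
#' 9. Kaplan-Meier/log-rank evaluation and Cox independence analysis
#'    against available clinical covariates.
#'
#' All randomness (fold assignments of the Lasso step) derives from `seed`;
#' identical inputs and seed reproduce the fit exactly.
#'
#' @param expr an [expression_set()] with normal and tumor samples and
#'   `gene_class` distinguishing lncRNAs from mRNAs.
#' @param clinical data.frame with columns `sample_id`, `time` (days),
#'   `event` (0/1) and optionally numeric-coded covariates (e.g. `age`,
#'   `grade`, `stage`) for the tumor samples.
#' @param srg_ids character vector of SRG gene IDs (rows of `expr`).
#' @param control a [signature_control()].
#' @param seed master seed for the selection step.
#' @return An object of class `pair_signature`; see
#'   [print.pair_signature()], [summary.pair_signature()],
#'   [predict.pair_signature()], [plot.pair_signature()]. Key elements:
#'   `model` (`signature_model`), `score`, `cutoff`, `risk_group`, `rocs`,
#'   `aucs`, `km`, `independence`, `funnel` (named stage counts), `de`,
#'   `coex`, `screen`, `lasso`.
#' @export
pair_signature <- function(expr, clinical, srg_ids,
                           control = signature_control(), seed = 1L) {
  stopifnot(inherits(expr, "expr_set"), inherits(control, "signature_control"))
  for (col in c("sample_id", "time", "event"))
    if (!col %in% names(clinical))
      stop("clinical table lacks required column `", col, "`")
  tumor_ids <- names(expr$sample_group)[expr$sample_group == "tumor"]
  clin <- clinical[match(intersect(tumor_ids, clinical$sample_id),
                         clinical$sample_id), , drop = FALSE]
  if (nrow(clin) < 10)
    stop("fewer than 10 tumor samples with clinical follow-up")
  if (any(!is.finite(clin$time)) || any(clin$time <= 0))
    stop("clinical `time` must be positive and finite")
  if (!all(clin$event %in% c(0, 1))) stop("clinical `event` must be 0/1")

  lnc <- expr$values[expr$gene_class == "lncRNA", , drop = FALSE]
  srg_ids <- intersect(srg_ids, rownames(expr$values))
  if (length(srg_ids) < 1) stop("no SRG ID found in the expression matrix")
  srg <- expr$values[srg_ids, , drop = FALSE]

  # 1-2: screens
  de <- differential_expression(lnc, fc_min = control$fc_min,
                                fdr_max = control$fdr_max,
                                method = control$de_method,
                                pseudocount = control$pseudocount,
                                sample_group = expr$sample_group)
  tum <- clin$sample_id
  coex <- coexpression_screen(lnc[, tum, drop = FALSE],
                              srg[, tum, drop = FALSE],
                              rho_min = control$rho_min,
                              p_max = control$rho_p_max,
                              signed = control$rho_signed)
  candidates <- select_desrlnc(de, coex)
  if (length(candidates) < 2)
    stop("fewer than 2 candidate lncRNAs survive the screens; ",
         "pipeline halted")

  # 4: pair matrix on the survival cohort
  pm_all <- build_pair_matrix(lnc[candidates, tum, drop = FALSE])
  pm <- filter_valid_pairs(pm_all, control$pair_low, control$pair_high)
  if (ncol(pm$values) < 2)
    stop("fewer than 2 valid pairs after the one-fraction filter")

  # 5: univariate screen
  screen <- univariate_screen(pm, clin$time, clin$event,
                              p_max = control$screen_p_max,
                              adjust = control$screen_adjust)
  if (length(screen$kept) < 2)
    stop("fewer than 2 pairs pass the univariate Cox screen")
  pm_screen <- subset_pairs(pm, screen$kept)

  # 6: penalised stability selection
  lasso <- lasso_frequency_select(pm_screen$values, clin$time, clin$event,
                                  n_reps = control$n_reps,
                                  n_folds = control$n_folds,
                                  freq_min = control$freq_min,
                                  seed = seed,
                                  lambda_rule = control$lambda_rule)
  sel <- names(lasso$selected)[lasso$selected]
  if (length(sel) < 1)
    stop("no pair exceeded the Lasso selection frequency threshold")

  # 7: stepwise multivariate model
  model <- stepwise_cox(pm_screen$values[, sel, drop = FALSE],
                        clin$time, clin$event,
                        provenance = list(seed = seed,
                                          control = unclass(control)))
  if (nrow(model$pairs) == 0)
    stop("stepwise elimination removed every pair; no signature")

  # 8: risk score, cutoff, groups
  score <- compute_riskscore(model, pm)
  cutoff <- aic_optimal_cutoff(score, clin$time, clin$event,
                               horizon = control$cutoff_horizon,
                               min_group_frac = control$min_group_frac,
                               method = control$cutoff_method)
  risk_group <- stratify(score, cutoff$cutoff)

  # 9: evaluation
  rocs <- lapply(control$horizons, function(h)
    tryCatch(time_dependent_roc(score, clin$time, clin$event, h),
             error = function(e) NULL))
  names(rocs) <- paste0(round(control$horizons / 365, 2), "y")
  aucs <- vapply(rocs, function(r) if (is.null(r)) NA_real_ else r$auc,
                 numeric(1))
  km <- kaplan_meier(clin$time, clin$event, risk_group)
  covar_cols <- intersect(c("age", "grade", "stage"), names(clin))
  covar_cols <- covar_cols[vapply(clin[covar_cols], is.numeric, logical(1))]
  independence <- if (length(covar_cols))
    independence_cox(score, clin[covar_cols], clin$time, clin$event)

  funnel <- c(lncRNAs = nrow(lnc),
              de_lncRNAs = sum(de$direction != "ns"),
              coexpressed_lncRNAs = sum(coex$kept),
              candidates = length(candidates),
              pairs_enumerated = ncol(pm_all$values),
              pairs_valid = ncol(pm$values),
              pairs_screened = length(screen$kept),
              pairs_lasso = length(sel),
              pairs_signature = nrow(model$pairs))

  structure(list(model = model, funnel = funnel, candidates = candidates,
                 de = de, coex = coex, pair_matrix = pm, screen = screen,
                 lasso = lasso, score = score, cutoff = cutoff,
                 risk_group = risk_group, rocs = rocs, aucs = aucs,
                 km = km, independence = independence,
                 clinical = clin, control = control, seed = seed,
                 call = match.call()),
            class = "pair_signature")
}

#' @describeIn pair_signature Fit directly from a simulated cohort.
#' @param sim a `sim_cohort` from [simulate_cohort()].
#' @param ... passed on to `pair_signature()`.
#' @export
pair_signature_sim <- function(sim, ...) {
  stopifnot(inherits(sim, "sim_cohort"))
  pair_signature(sim$expr, sim$clinical, sim$srg_ids, ...)
}

#' Print a fitted pair signature
#'
#' @param x a `pair_signature`.
#' @param ... unused.
#' @export
print.pair_signature <- function(x, ...) {
  cat("Prognostic lncRNA-pair signature\n")
  cat("  funnel: ", paste(names(x$funnel), x$funnel, sep = " = ",
                          collapse = ", "), "\n", sep = "")
  cat("  signature pairs: ", nrow(x$model$pairs),
      "; cutoff = ", signif(x$cutoff$cutoff, 4),
      " (", x$cutoff$method, ")\n", sep = "")
  cat("  risk groups: low = ", sum(x$risk_group == "low"),
      ", high = ", sum(x$risk_group == "high"), "\n", sep = "")
  cat("  AUC:", paste(names(x$aucs), round(x$aucs, 3), sep = " = ",
                      collapse = ", "), "\n")
  cat("  log-rank p =", signif(x$km$logrank_p, 3), "\n")
  invisible(x)
}

#' Summarise a fitted pair signature
#'
#' @param object a `pair_signature`.
#' @param ... unused.
#' @return list of class `summary.pair_signature` with the coefficient
#'   table (pair, coefficient, HR, 95% CI, Wald p), stage funnel, AUCs,
#'   cutoff, group sizes, log-rank test and the independence table.
#' @export
summary.pair_signature <- function(object, ...) {
  fit <- object$model$fit
  coef_table <- data.frame(pair = names(object$model$coefficients),
                           coef = object$model$coefficients,
                           hr = fit$hr,
                           lo95 = fit$ci95[, "lo"], hi95 = fit$ci95[, "hi"],
                           p = fit$wald_p, row.names = NULL)
  structure(list(coef_table = coef_table, funnel = object$funnel,
                 aucs = object$aucs, cutoff = object$cutoff$cutoff,
                 group_sizes = table(object$risk_group),
                 logrank_chi2 = object$km$logrank_chi2,
                 logrank_p = object$km$logrank_p,
                 median_survival = object$km$median_survival,
                 independence = if (!is.null(object$independence))
                   object$independence$table),
            class = "summary.pair_signature")
}

#' @export
print.summary.pair_signature <- function(x, ...) {
  cat("Signature pairs:\n")
  tab <- x$coef_table
  tab$coef <- round(tab$coef, 3); tab$hr <- round(tab$hr, 3)
  tab$lo95 <- round(tab$lo95, 3); tab$hi95 <- round(tab$hi95, 3)
  tab$p <- signif(tab$p, 3)
  print(tab)
  cat("\nCutoff:", signif(x$cutoff, 4), "-> groups:",
      paste(names(x$group_sizes), x$group_sizes, sep = " = ",
            collapse = ", "), "\n")
  cat("AUC:", paste(names(x$aucs), round(x$aucs, 3), sep = " = ",
                    collapse = ", "), "\n")
  cat("Log-rank chi2 =", round(x$logrank_chi2, 3),
      ", p =", signif(x$logrank_p, 3), "\n")
  if (!is.null(x$independence)) {
    cat("\nIndependence analysis:\n")
    tab <- x$independence
    tab$hr <- round(tab$hr, 3); tab$lo95 <- round(tab$lo95, 3)
    tab$hi95 <- round(tab$hi95, 3); tab$p <- signif(tab$p, 3)
    print(tab)
  }
  invisible(x)
}

#' @export
coef.pair_signature <- function(object, ...) object$model$coefficients

#' Predict risk scores or risk groups for new samples
#'
#' Evaluates the fitted signature on new expression data: the signature
#' pair indicators are recomputed on the new samples and combined with the
#' fitted coefficients; `type = "group"` additionally applies the stored
#' cutoff.
#'
#' @param object a `pair_signature`.
#' @param newdata an [expression_set()] or genes x samples matrix
#'   containing every signature gene; defaults to the training scores.
#' @param type `"score"` (default) or `"group"`.
#' @param ... unused.
#' @return named numeric scores, or a `low`/`high` factor.
#' @export
predict.pair_signature <- function(object, newdata = NULL,
                                   type = c("score", "group"), ...) {
  type <- match.arg(type)
  score <- if (is.null(newdata)) object$score else
    compute_riskscore(object$model,
                      pair_indicators(newdata, object$model$pairs))
  if (type == "score") score else stratify(score, object$cutoff$cutoff)
}

#' Martingale residuals of the final multivariate Cox fit
#'
#' @param object a `pair_signature`.
#' @param ... passed to [survival::residuals.coxph()].
#' @export
residuals.pair_signature <- function(object, ...) {
  stats::residuals(object$model$fit$object, ...)
}

#' Plot a fitted pair signature
#'
#' `which = "km"` draws the Kaplan-Meier curves of the two risk groups;
#' `which = "roc"` overlays the time-dependent ROC curves at the configured
#' horizons; `which = "cutoff"` shows the AIC (or Youden) trace over
#' candidate cutoffs.
#'
#' @param x a `pair_signature`.
#' @param which `"km"`, `"roc"` or `"cutoff"`.
#' @param ... further graphical parameters.
#' @export
plot.pair_signature <- function(x, which = c("km", "roc", "cutoff"), ...) {
  which <- match.arg(which)
  if (which == "km") {
    cols <- c(low = "#2166AC", high = "#B2182B")
    plot(NA, xlim = c(0, max(x$clinical$time)), ylim = c(0, 1),
         xlab = "Days", ylab = "Survival probability",
         main = "Risk-group survival", ...)
    for (g in names(x$km$curves)) {
      cv <- x$km$curves[[g]]
      graphics::lines(stats::stepfun(cv$time, c(1, cv$surv)),
                      do.points = FALSE, col = cols[[g]], lwd = 2)
    }
    graphics::legend("topright", legend = paste0(
      names(x$km$curves), " (n=", vapply(x$km$curves, function(cv)
        max(cv$n_risk), numeric(1)), ")"),
      col = cols[names(x$km$curves)], lwd = 2, bty = "n")
    graphics::mtext(sprintf("log-rank p = %.2g", x$km$logrank_p), cex = 0.8)
  } else if (which == "roc") {
    plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
         xlab = "1 - specificity", ylab = "Sensitivity",
         main = "Time-dependent ROC", ...)
    cols <- grDevices::hcl.colors(length(x$rocs), "Dark 3")
    for (i in seq_along(x$rocs)) {
      r <- x$rocs[[i]]
      if (is.null(r)) next
      ord <- order(r$thresholds, decreasing = TRUE)
      graphics::lines((1 - r$specificity)[ord], r$sensitivity[ord],
                      col = cols[i], lwd = 2)
    }
    graphics::legend("bottomright", legend = sprintf(
      "%s AUC = %.3f", names(x$rocs), x$aucs), col = cols, lwd = 2,
      bty = "n")
  } else {
    tr <- x$cutoff$trace
    plot(tr$cutoff, tr$criterion, type = "b", pch = 16, cex = 0.6,
         xlab = "Candidate cutoff",
         ylab = if (x$cutoff$method == "aic") "AIC" else "-Youden index",
         main = "Cutoff search", ...)
    graphics::abline(v = x$cutoff$cutoff, col = "#B2182B", lty = 2)
  }
  invisible(x)
}
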