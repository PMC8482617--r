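#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`: standard
#' step-up adjusted p-values, monotone in rank order and capped at 1.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted values, same length and order.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03))
#' @export
benjamini_hochberg <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Differential expression between tumor and normal samples
#'
#' Two-group comparison on `log2(x + pseudocount)`. The default moderated t
#' shrinks each gene's pooled two-group variance toward an empirical-Bayes
#' prior: the per-gene variances are modelled as scaled F-draws and the
#' prior degrees of freedom `d0` and scale `s0^2` are estimated by the
#' method of moments from the log sample variances (via
#' [limma::fitFDist()]); the posterior variance is
#' `(d0 * s0^2 + d * s^2) / (d0 + d)` and the moderated t is referenced to a
#' t distribution on `d0 + d` degrees of freedom. `prior_df = 0` recovers
#' the ordinary pooled-variance two-sample t exactly. `method = "welch_t"`
#' performs a per-gene Welch test instead.
#'
#' A gene with identical values in every sample has an undefined t and is
#' reported with `p_value = 1` and direction `ns`.
#'
#' @param expr an [expression_set()] with both groups present (at least 2
#'   samples each), or a numeric matrix together with `sample_group`.
#' @param fc_min minimum absolute log2 fold change (strict) for a gene to be
#'   called up/down.
#' @param fdr_max maximum BH-adjusted p (strict) for a gene to be called.
#' @param method `"moderated_t"` (default) or `"welch_t"`.
#' @param pseudocount added before the log2 transform; default 1.
#' @param prior_df optional override of the estimated prior degrees of
#'   freedom (moderated t only); `0` gives the ordinary pooled t.
#' @param sample_group group labels when `expr` is a bare matrix.
#' @return data.frame with one row per gene: `gene_id`, `log2fc` (tumor
#'   minus normal), `t_stat`, `p_value`, `fdr`, `direction` in
#'   `{"up", "down", "ns"}`.
#' @export
differential_expression <- function(expr, fc_min = 1, fdr_max = 0.01,
                                    method = c("moderated_t", "welch_t"),
                                    pseudocount = 1, prior_df = NULL,
                                    sample_group = NULL) {
  method <- match.arg(method)
  if (inherits(expr, "expr_set")) {
    sample_group <- expr$sample_group
    expr <- expr$values
  }
  if (is.null(sample_group))
    stop("`sample_group` required when `expr` is a matrix")
  grp <- factor(as.character(sample_group), levels = c("normal", "tumor"))
  n1 <- sum(grp == "tumor", na.rm = TRUE)
  n0 <- sum(grp == "normal", na.rm = TRUE)
  if (n1 < 2 || n0 < 2)
    stop("each group needs at least 2 samples (tumor = ", n1,
         ", normal = ", n0, ")")
  lx <- log2(expr + pseudocount)
  xt <- lx[, grp == "tumor", drop = FALSE]
  xn <- lx[, grp == "normal", drop = FALSE]
  m1 <- rowMeans(xt)
  m0 <- rowMeans(xn)
  log2fc <- m1 - m0
  v1 <- apply(xt, 1, stats::var)
  v0 <- apply(xn, 1, stats::var)

  if (method == "moderated_t") {
    d <- n1 + n0 - 2
    s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / d
    pos <- s2 > 0
    if (sum(pos) >= 2) {
      fd <- limma::fitFDist(s2[pos], df1 = d)
      d0 <- fd$df2
      s02 <- fd$scale
    } else {
      d0 <- 0
      s02 <- 1
    }
    if (!is.null(prior_df)) d0 <- prior_df
    # reference df capped at the pooled residual df across genes
    df_pooled <- d * length(s2)
    if (!is.finite(d0)) {
      var_post <- rep(s02, length(s2))
      df_total <- rep(df_pooled, length(s2))
    } else {
      var_post <- (d0 * s02 + d * s2) / (d0 + d)
      df_total <- rep(min(d0 + d, df_pooled), length(s2))
    }
    t_stat <- log2fc / sqrt(var_post * (1 / n1 + 1 / n0))
    p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    t_stat <- log2fc / se
    df_w <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
    p <- 2 * stats::pt(-abs(t_stat), df = df_w)
  }
  # degenerate genes: identical everywhere -> undefined t, p = 1 by policy;
  # noiseless between-group shift -> p = 0
  zero_var <- v1 == 0 & v0 == 0
  p[zero_var & log2fc != 0 & !is.finite(p)] <- 0
  p[zero_var & log2fc == 0] <- 1
  t_stat[zero_var & log2fc == 0] <- NA_real_
  p[!is.finite(p)] <- 1
  fdr <- benjamini_hochberg(p)
  direction <- ifelse(abs(log2fc) > fc_min & fdr < fdr_max,
                      ifelse(log2fc > 0, "up", "down"), "ns")
  data.frame(gene_id = rownames(expr), log2fc = log2fc, t_stat = t_stat,
             p_value = p, fdr = fdr, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

# internal: Spearman rho (mid-ranks) between all rows of two matrices, with
# t-approximation p-values. Constant rows get NA with a warning upstream.
spearman_matrix <- function(a, b) {
  n <- ncol(a)
  ra <- t(apply(a, 1, rank))
  rb <- t(apply(b, 1, rank))
  sda <- apply(ra, 1, stats::sd)
  sdb <- apply(rb, 1, stats::sd)
  rho <- suppressWarnings(stats::cor(t(ra), t(rb)))
  rho[sda == 0, ] <- NA_real_
  rho[, sdb == 0] <- NA_real_
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, 0))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[is.nan(p) | is.infinite(tt)] <- 0  # |rho| = 1
  p[is.na(rho)] <- NA_real_
  list(rho = rho, p = p)
}

#' Coexpression screen of lncRNAs against stemness-related genes
#'
#' Spearman rank correlation (mid-ranks, t-approximation p-value) between
#' every lncRNA and every SRG, computed sample-wise over the columns of the
#' two matrices (callers pass tumor samples only; the disease context is
#' what the screen is about). A lncRNA is kept when at least one SRG partner
#' satisfies `|rho| > rho_min` and `p <= p_max` (or `rho > rho_min` with
#' `signed = TRUE`).
#'
#' @param lnc_expr numeric matrix, lncRNAs x samples.
#' @param srg_expr numeric matrix, SRGs x samples, same samples in the same
#'   order.
#' @param rho_min correlation threshold (strict); default 0.4.
#' @param p_max p-value threshold (inclusive); default 0.05.
#' @param signed if `TRUE` only positive correlations qualify.
#' @return list of class `coexpression_result`: `rho` and `p` matrices
#'   (lncRNA x SRG), `kept` named logical per lncRNA, and the thresholds.
#' @export
coexpression_screen <- function(lnc_expr, srg_expr, rho_min = 0.4,
                                p_max = 0.05, signed = FALSE) {
  if (ncol(lnc_expr) != ncol(srg_expr) ||
      !identical(colnames(lnc_expr), colnames(srg_expr)))
    stop("lncRNA and SRG matrices must share the same samples in order")
  if (ncol(lnc_expr) < 4)
    stop("at least 4 samples are required for the correlation screen")
  sp <- spearman_matrix(lnc_expr, srg_expr)
  if (anyNA(sp$rho))
    warning("constant expression vectors: ",
            sum(apply(lnc_expr, 1, stats::sd) == 0), " lncRNA(s) and ",
            sum(apply(srg_expr, 1, stats::sd) == 0),
            " SRG(s) skipped (rho undefined)")
  qual <- if (signed) sp$rho > rho_min else abs(sp$rho) > rho_min
  pass <- qual & sp$p <= p_max
  kept <- apply(pass, 1, function(z) any(z, na.rm = TRUE))
  structure(list(rho = sp$rho, p = sp$p,
                 kept = stats::setNames(kept, rownames(lnc_expr)),
                 rho_min = rho_min, p_max = p_max, signed = signed),
            class = "coexpression_result")
}

#' @export
print.coexpression_result <- function(x, ...) {
  cat("Coexpression screen:", nrow(x$rho), "lncRNAs x", ncol(x$rho),
      "SRGs;", sum(x$kept), "lncRNAs kept (",
      if (x$signed) "rho > " else "|rho| > ", x$rho_min,
      ", p <= ", x$p_max, ")\n", sep = "")
  invisible(x)
}

#' Intersect the differential-expression and coexpression screens
#'
#' A candidate (a differentially expressed stemness-related lncRNA) is a
#' lncRNA called up or down by [differential_expression()] AND kept by
#' [coexpression_screen()]. Both filters are per-gene, so the intersection
#' does not depend on the order in which they are applied.
#'
#' @param de a data.frame from [differential_expression()].
#' @param coex a `coexpression_result`.
#' @return sorted character vector of candidate lncRNA IDs (possibly empty,
#'   with a warning).
#' @export
select_desrlnc <- function(de, coex) {
  stopifnot(is.data.frame(de), inherits(coex, "coexpression_result"))
  de_ids <- de$gene_id[de$direction != "ns"]
  coex_ids <- names(coex$kept)[coex$kept]
  out <- sort(intersect(de_ids, coex_ids))
  if (length(out) == 0)
    warning("no lncRNA passed both the DE and coexpression screens")
  out
}
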