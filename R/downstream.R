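#' Compare features between risk groups with the Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per feature between two
#' groups, as used for immune-checkpoint expression, externally computed
#' drug-sensitivity (IC50) and immunophenoscore tables. The exact null
#' distribution is enumerated when both groups have at most 8 non-missing,
#' tie-free values; otherwise the mid-rank normal approximation with
#' continuity correction is used. BH adjustment across features by default.
#'
#' @param features numeric matrix or data.frame, samples x features;
#'   missing values are dropped per feature.
#' @param groups factor with exactly 2 non-empty levels, aligned to the
#'   rows of `features`.
#' @param adjust `"bh"` (default) or `"none"`.
#' @return data.frame with one row per tested feature: `feature`, `n1`,
#'   `n2` (per-group non-missing counts, first level first), `U` (statistic
#'   for the first group), `p`, `p_adj`, `direction` (`"up"` when the first
#'   level's median is higher, `"down"` lower, `"none"` equal). Features
#'   with fewer than 2 values in a group are skipped with a warning.
#' @export
group_compare <- function(features, groups, adjust = c("bh", "none")) {
  adjust <- match.arg(adjust)
  features <- as.matrix(as.data.frame(features))
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2)
    stop("exactly 2 non-empty groups are required (got ",
         nlevels(groups), ")")
  if (nrow(features) != length(groups))
    stop("`features` rows must align with `groups`")
  g1 <- levels(groups)[1]
  rows <- lapply(colnames(features), function(f) {
    v <- features[, f]
    x <- v[groups == g1 & !is.na(v)]
    y <- v[groups != g1 & !is.na(v)]
    if (length(x) < 2 || length(y) < 2) {
      warning("feature `", f, "` skipped: fewer than 2 values in a group")
      return(NULL)
    }
    exact <- length(x) <= 8 && length(y) <= 8 &&
      !any(duplicated(c(x, y)))
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    med_diff <- stats::median(x) - stats::median(y)
    data.frame(feature = f, n1 = length(x), n2 = length(y),
               U = unname(wt$statistic), p = wt$p.value,
               direction = if (med_diff > 0) "up" else
                 if (med_diff < 0) "down" else "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no feature could be tested")
  out$p_adj <- if (adjust == "bh") benjamini_hochberg(out$p) else out$p
  rownames(out) <- NULL
  out[, c("feature", "n1", "n2", "U", "p", "p_adj", "direction")]
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Mid-rank Spearman rho between two paired vectors (e.g. risk score vs
#' tumor mutation burden), with the t-approximation p-value
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Missing pairs are dropped.
#'
#' @param x,y paired numeric vectors; at least 4 complete pairs.
#' @return list with `rho`, `p`, `n`.
#' @examples
#' rank_correlation(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
#' @export
rank_correlation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("at least 4 complete pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: Spearman rho is undefined")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), df = n - 2), n = n)
}
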