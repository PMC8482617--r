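#' Build the 0/1 pair-indicator matrix
#'
#' Every unordered couple of candidate lncRNAs becomes one binary feature:
#' for pair `(A, B)` in canonical (lexicographic) order, a sample scores 1
#' when the expression of `A` is strictly higher than that of `B`, else 0
#' (ties score 0). The indicator depends only on the within-sample ordering
#' of the two genes, so any strictly increasing per-sample transform of
#' expression — including per-sample normalisation — leaves the matrix
#' unchanged. `K` candidates yield `K * (K - 1) / 2` columns.
#'
#' @param expr numeric matrix of candidate lncRNAs x samples (typically the
#'   tumor samples of the survival cohort), or an [expression_set()] whose
#'   rows are the candidates.
#' @return An object of class `pair_matrix`: list with `values` (samples x
#'   pairs integer 0/1 matrix, columns named `"A|B"`), `pairs` (data.frame
#'   `lnc_a`, `lnc_b`), and `one_fraction` (per-pair column mean).
#' @examples
#' m <- rbind(G1 = c(5, 1), G2 = c(3, 4))
#' colnames(m) <- c("S1", "S2")
#' build_pair_matrix(m)$values
#' @export
build_pair_matrix <- function(expr) {
  if (inherits(expr, "expr_set")) expr <- expr$values
  if (!is.matrix(expr) || nrow(expr) < 2)
    stop("at least 2 candidate lncRNAs are required for pairing")
  if (is.null(rownames(expr))) stop("candidate matrix must have gene IDs")
  expr <- expr[order(rownames(expr)), , drop = FALSE]
  k <- nrow(expr)
  idx <- utils::combn(k, 2)
  a <- rownames(expr)[idx[1, ]]
  b <- rownames(expr)[idx[2, ]]
  values <- t((expr[idx[1, ], , drop = FALSE] >
                 expr[idx[2, ], , drop = FALSE]) * 1L)
  dimnames(values) <- list(colnames(expr), paste(a, b, sep = "|"))
  new_pair_matrix(values, data.frame(lnc_a = a, lnc_b = b,
                                     stringsAsFactors = FALSE))
}

new_pair_matrix <- function(values, pairs) {
  storage.mode(values) <- "integer"
  structure(list(values = values, pairs = pairs,
                 one_fraction = colMeans(values)),
            class = "pair_matrix")
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat("Pair matrix:", nrow(x$values), "samples x", ncol(x$values),
      "lncRNA pairs\n")
  if (ncol(x$values))
    cat("  one-fraction range: [",
        round(min(x$one_fraction), 3), ", ",
        round(max(x$one_fraction), 3), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.pair_matrix <- function(x) dim(x$values)

#' Keep pairs whose indicator is informative across the cohort
#'
#' A pair whose indicator is (almost) always 0 or always 1 carries no rank
#' information and cannot separate patients. A pair is valid when the
#' fraction of samples scoring 1 lies strictly between `low` and `high`
#' (defaults 20% and 80%). Filtering is idempotent and preserves column
#' order.
#'
#' @param pm a `pair_matrix`.
#' @param low,high open-interval bounds on the one-fraction; `low < high`.
#' @return The filtered `pair_matrix`.
#' @export
filter_valid_pairs <- function(pm, low = 0.2, high = 0.8) {
  stopifnot(inherits(pm, "pair_matrix"))
  if (!(low < high)) stop("`low` must be strictly less than `high`")
  keep <- pm$one_fraction > low & pm$one_fraction < high
  subset_pairs(pm, keep)
}

#' Subset a pair matrix by column
#'
#' @param pm a `pair_matrix`.
#' @param which logical, integer or character (column-name) index.
#' @return The restricted `pair_matrix`.
#' @export
subset_pairs <- function(pm, which) {
  stopifnot(inherits(pm, "pair_matrix"))
  if (is.character(which)) which <- match(which, colnames(pm$values))
  if (anyNA(which)) stop("unknown pair column(s) requested")
  if (is.logical(which)) which <- which(which)
  new_pair_matrix(pm$values[, which, drop = FALSE],
                  pm$pairs[which, , drop = FALSE])
}

#' Evaluate given pair definitions on new expression data
#'
#' Computes the 0/1 indicators for a fixed list of pairs (for example the
#' pairs of a fitted signature) on a new genes x samples matrix. Used by
#' `predict()` on fitted signatures.
#'
#' @param expr numeric matrix (genes x samples) or [expression_set()]
#'   containing every gene named in `pairs`.
#' @param pairs data.frame with columns `lnc_a`, `lnc_b`.
#' @return A `pair_matrix` with one column per requested pair, in order.
#' @export
pair_indicators <- function(expr, pairs) {
  if (inherits(expr, "expr_set")) expr <- expr$values
  need <- unique(c(pairs$lnc_a, pairs$lnc_b))
  missing <- setdiff(need, rownames(expr))
  if (length(missing))
    stop("genes absent from expression matrix: ",
         paste(missing, collapse = ", "))
  values <- t((expr[pairs$lnc_a, , drop = FALSE] >
                 expr[pairs$lnc_b, , drop = FALSE]) * 1L)
  dimnames(values) <- list(colnames(expr),
                           paste(pairs$lnc_a, pairs$lnc_b, sep = "|"))
  new_pair_matrix(values, pairs[, c("lnc_a", "lnc_b"), drop = FALSE])
}
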