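#' Expression set container
#'
#' Light container for a genes x samples expression matrix together with the
#' per-sample normal/tumor annotation and the per-gene RNA class. Values are
#' non-negative continuous abundances (FPKM-like); all statistics downstream
#' are computed either on `log2(x + pseudocount)` or on within-sample ranks.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique non-empty dimnames. Values must be finite and `>= 0`.
#' @param sample_group character or factor of length `ncol(values)` with
#'   levels `"normal"` and `"tumor"`.
#' @param gene_class character or factor of length `nrow(values)` with
#'   levels `"lncRNA"` and `"mRNA"`.
#' @return An object of class `expr_set`: a list with elements `values`,
#'   `sample_group` and `gene_class`.
#' @examples
#' m <- matrix(rexp(12), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' es <- expression_set(m, rep(c("normal", "tumor"), 2),
#'                      c("lncRNA", "lncRNA", "mRNA"))
#' es
#' @export
expression_set <- function(values, sample_group, gene_class) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs in `values`")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs in `values`")
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and >= 0")
  sample_group <- factor(as.character(sample_group),
                         levels = c("normal", "tumor"))
  if (length(sample_group) != ncol(values) || anyNA(sample_group))
    stop("`sample_group` must label every sample as 'normal' or 'tumor'")
  gene_class <- factor(as.character(gene_class), levels = c("lncRNA", "mRNA"))
  if (length(gene_class) != nrow(values) || anyNA(gene_class))
    stop("`gene_class` must label every gene as 'lncRNA' or 'mRNA'")
  structure(list(values = values,
                 sample_group = stats::setNames(sample_group, colnames(values)),
                 gene_class = stats::setNames(gene_class, rownames(values))),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("Expression set:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  cat("  genes:  ", sum(x$gene_class == "lncRNA"), "lncRNA,",
      sum(x$gene_class == "mRNA"), "mRNA\n")
  cat("  samples:", sum(x$sample_group == "tumor"), "tumor,",
      sum(x$sample_group == "normal"), "normal\n")
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' Subset an expression set by genes and/or samples
#'
#' @param x an `expr_set`.
#' @param genes,samples character vectors of IDs (or logical/integer indices).
#' @return An `expr_set` restricted to the requested rows/columns.
#' @export
subset_expression <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_set"))
  if (is.null(genes)) genes <- seq_len(nrow(x$values))
  if (is.null(samples)) samples <- seq_len(ncol(x$values))
  expression_set(x$values[genes, samples, drop = FALSE],
                 x$sample_group[samples],
                 x$gene_class[genes])
}

# internal: values for tumor samples only
tumor_values <- function(x) {
  x$values[, x$sample_group == "tumor", drop = FALSE]
}
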