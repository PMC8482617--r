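#' Read an expression matrix with sample annotation from TSV
#'
#' `path` is a tab-separated table whose first column `gene_id` holds gene
#' IDs and whose remaining columns are samples. `annotation` is a TSV with
#' columns `sample_id` and `group` (`normal`/`tumor`). Genes listed in
#' `lnc_ids` are classed as lncRNA, all others as mRNA.
#'
#' @param path expression TSV path.
#' @param annotation sample-annotation TSV path.
#' @param lnc_ids character vector of lncRNA gene IDs.
#' @return An [expression_set()].
#' @export
read_expression_tsv <- function(path, annotation, lnc_ids) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id")
    stop("expression TSV must start with a `gene_id` column")
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab$gene_id
  anno <- utils::read.delim(annotation, stringsAsFactors = FALSE)
  for (col in c("sample_id", "group"))
    if (!col %in% names(anno))
      stop("annotation TSV lacks required column `", col, "`")
  grp <- anno$group[match(colnames(values), anno$sample_id)]
  if (anyNA(grp)) stop("annotation missing for some samples")
  expression_set(values, grp,
                 ifelse(rownames(values) %in% lnc_ids, "lncRNA", "mRNA"))
}

#' Read a clinical table from TSV
#'
#' Requires columns `sample_id`, `time` and `event`; any further columns
#' (e.g. `age`, `grade`, `stage`) are kept.
#'
#' @param path clinical TSV path.
#' @return data.frame.
#' @export
read_clinical_tsv <- function(path) {
  clin <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("sample_id", "time", "event"))
    if (!col %in% names(clin))
      stop("clinical TSV lacks required column `", col, "`")
  clin
}

#' Read a gene ID list (one ID per line)
#'
#' @param path text file path.
#' @return character vector of unique, non-empty IDs.
#' @export
read_gene_list <- function(path) {
  ids <- trimws(readLines(path))
  unique(ids[nzchar(ids)])
}

#' Write the per-sample risk table to TSV
#'
#' Columns `sample_id`, `score`, `group`.
#'
#' @param fit a `pair_signature`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_risk_table <- function(fit, path) {
  stopifnot(inherits(fit, "pair_signature"))
  utils::write.table(
    data.frame(sample_id = names(fit$score), score = fit$score,
               group = as.character(fit$risk_group)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
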