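#' Construct an expression study
#'
#' An `expression_study` holds one study's gene-by-sample matrix of
#' log2-scale expression values. Missing measurements are stored as `NA`;
#' the missing mask is always `is.na(values)`.
#'
#' @param values Numeric matrix, genes as rows and samples as columns.
#'   Row names are taken as gene identifiers and column names as sample
#'   identifiers unless `gene_ids`/`sample_ids` are given.
#' @param study_id Character scalar identifying the study.
#' @param gene_ids Optional character vector of gene identifiers.
#' @param sample_ids Optional character vector of sample identifiers.
#' @return An object of class `expression_study` with fields `study_id`,
#'   `gene_ids`, `sample_ids` and `values`.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' expression_study(m, "demo")
#' @export
expression_study <- function(values, study_id = "study",
                             gene_ids = rownames(values),
                             sample_ids = colnames(values)) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("length of 'gene_ids' must equal the number of rows")
  if (length(sample_ids) != ncol(values))
    stop("length of 'sample_ids' must equal the number of columns")
  if (anyDuplicated(gene_ids))
    stop("gene identifiers must be unique")
  if (anyDuplicated(sample_ids))
    stop("sample identifiers must be unique")
  if (any(is.infinite(values)))
    stop("non-missing expression values must be finite")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(study_id = as.character(study_id)[1],
         gene_ids = gene_ids,
         sample_ids = sample_ids,
         values = values),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study '%s': %d genes x %d samples (%.1f%% missing)\n",
              x$study_id, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$values)

#' Missing-value mask of an expression study
#'
#' @param study An `expression_study`.
#' @return Logical matrix, `TRUE` where the measurement is missing.
#' @export
missing_mask <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  is.na(study$values)
}
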