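#' Log-transform an expression matrix if it looks linear-scale
#'
#' Expression tables deposited in public repositories are sometimes on a
#' linear scale and sometimes already log-transformed. Log2 expression rarely
#' exceeds ~20, so a matrix whose upper tail reaches far beyond that is taken
#' to be linear-scale: if the 99th percentile of non-missing values exceeds
#' 30, the matrix is transformed as `log2(x + 1)` (negative values are
#' clipped to 0 first); otherwise it is returned unchanged.
#'
#' @param values Numeric matrix with `NA` for missing entries.
#' @param threshold Percentile value above which the transform is applied.
#' @return A list with `values` (possibly transformed matrix) and `applied`
#'   (logical flag).
#' @export
maybe_log_transform <- function(values, threshold = 30) {
  if (!is.matrix(values)) values <- as.matrix(values)
  v <- values[!is.na(values)]
  if (length(v) == 0L) stop("matrix has no non-missing values")
  q99 <- stats::quantile(v, 0.99, names = FALSE, type = 7)
  if (q99 > threshold) {
    values[!is.na(values) & values < 0] <- 0
    list(values = log2(values + 1), applied = TRUE)
  } else {
    list(values = values, applied = FALSE)
  }
}

#' Median-polish decomposition of a two-way table
#'
#' Tukey's median polish decomposes a matrix into
#' `overall + row_effects + col_effects + residuals` by alternately sweeping
#' row and column medians, a robust two-way normalization classically used
#' for probe-level expression data. Missing cells are ignored by the median
#' sweeps. This wraps [stats::medpolish()].
#'
#' @param values Numeric matrix (may contain `NA`).
#' @param eps Relative convergence tolerance on the sum of absolute
#'   residuals.
#' @param max_iter Maximum number of full row+column sweeps.
#' @return A list with `overall`, `row_effects`, `col_effects`, `residuals`.
#' @examples
#' median_polish(matrix(c(1, 3, 2, 5), 2, 2))
#' @export
median_polish <- function(values, eps = 0.01, max_iter = 10) {
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot(eps > 0, max_iter >= 1)
  if (all(is.na(values))) stop("matrix has no non-missing values")
  fit <- stats::medpolish(values, eps = eps, maxiter = max_iter,
                          trace.iter = FALSE, na.rm = TRUE)
  list(overall = fit$overall,
       row_effects = fit$row,
       col_effects = fit$col,
       residuals = fit$residuals)
}

#' Normalize a study by median polish
#'
#' Applies [median_polish()] and returns the matrix with per-sample (column)
#' effects removed, i.e. `overall + row_effects + residuals`. Per-sample
#' effects bias gene-gene correlations; per-gene effects are retained since
#' Pearson correlation is invariant to them.
#'
#' @param study An `expression_study`.
#' @inheritParams median_polish
#' @return A normalized `expression_study`.
#' @export
normalize_study <- function(study, eps = 0.01, max_iter = 10) {
  stopifnot(inherits(study, "expression_study"))
  mp <- median_polish(study$values, eps = eps, max_iter = max_iter)
  vals <- mp$residuals + mp$overall + matrix(mp$row_effects,
                                             nrow(study$values),
                                             ncol(study$values))
  expression_study(vals, study$study_id, study$gene_ids, study$sample_ids)
}

#' Drop probes with too many missing values
#'
#' Rows whose fraction of missing values is strictly greater than
#' `threshold` are removed; surviving rows keep their order. A probe missing
#' in exactly `threshold` of the samples is kept.
#'
#' @param values Numeric probe-by-sample matrix with `NA` for missing.
#' @param threshold Maximum tolerated missing fraction, in `[0, 1)`.
#' @return The filtered matrix.
#' @export
filter_missing_probes <- function(values, threshold = 0.25) {
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot(threshold >= 0, threshold < 1)
  frac <- rowMeans(is.na(values))
  keep <- frac <= threshold
  if (!any(keep)) stop("all probes removed by missing-value filter: empty study")
  values[keep, , drop = FALSE]
}

#' Collapse probe-level rows to gene-level rows
#'
#' Probes mapping to the same gene are summarized by their per-sample
#' median over non-missing probe values; a gene-level cell is missing only
#' if every probe is missing there. Probes without a mapping, and probes
#' mapped to more than one gene (ambiguous), are dropped.
#'
#' @param values Numeric probe-by-sample matrix; row names are probe ids.
#' @param probe_to_gene Data frame (or two-column matrix) with columns
#'   `probe` and `gene`.
#' @param study_id Study identifier for the result.
#' @return An `expression_study` with one row per gene, genes in ascending
#'   identifier order.
#' @export
collapse_probes_to_genes <- function(values, probe_to_gene, study_id = "study") {
  if (!is.matrix(values)) values <- as.matrix(values)
  map <- as.data.frame(probe_to_gene, stringsAsFactors = FALSE)
  if (ncol(map) < 2 || nrow(map) == 0) stop("probe-to-gene mapping is empty")
  names(map)[1:2] <- c("probe", "gene")
  map$probe <- as.character(map$probe)
  map$gene <- as.character(map$gene)
  map <- unique(map[, c("probe", "gene")])
  # drop probes mapping to >1 gene
  multi <- unique(map$probe[duplicated(map$probe)])
  map <- map[!map$probe %in% multi, , drop = FALSE]
  map <- map[map$probe %in% rownames(values), , drop = FALSE]
  if (nrow(map) == 0) stop("no probes in the matrix have a usable gene mapping")
  genes <- sort(unique(map$gene))
  out <- matrix(NA_real_, length(genes), ncol(values),
                dimnames = list(genes, colnames(values)))
  gidx <- split(map$probe, map$gene)
  for (g in genes) {
    sub <- values[gidx[[g]], , drop = FALSE]
    med <- apply(sub, 2, stats::median, na.rm = TRUE)
    med[is.nan(med)] <- NA_real_
    out[g, ] <- med
  }
  expression_study(out, study_id)
}

#' Select a cross-platform gene panel
#'
#' Given the gene sets measured by each platform, counts for each gene the
#' number of platforms in which it appears, and keeps the `k` genes with the
#' highest count. Ties are broken by ascending gene identifier. If fewer
#' than `k` distinct genes exist, all are returned with a warning.
#'
#' @param platform_gene_sets List of character vectors, one per platform.
#' @param k Panel size (default 2000).
#' @return An object of class `gene_panel`: list with `gene_ids` (ordered
#'   by count descending then identifier ascending) and `platform_counts`.
#' @export
select_gene_panel <- function(platform_gene_sets, k = 2000) {
  stopifnot(length(platform_gene_sets) >= 1, k >= 1)
  counts <- table(unlist(lapply(platform_gene_sets,
                                function(s) unique(as.character(s)))))
  genes <- names(counts)
  ord <- order(-as.integer(counts), genes)
  genes <- genes[ord]
  counts <- as.integer(counts)[ord]
  if (length(genes) < k) {
    warning(sprintf("only %d genes available; panel smaller than requested k=%d",
                    length(genes), k))
  } else {
    genes <- genes[seq_len(k)]
    counts <- counts[seq_len(k)]
  }
  structure(list(gene_ids = genes,
                 platform_counts = stats::setNames(counts, genes)),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("gene_panel: %d genes\n", length(x$gene_ids)))
  invisible(x)
}

#' Restrict a study to a gene panel
#'
#' Reorders and subsets the study's rows to the panel order. Panel genes
#' absent from the study are recorded as all-missing rows, so that studies
#' on different platforms stay aligned on a common panel.
#'
#' @param study An `expression_study`.
#' @param panel A `gene_panel` or character vector of gene identifiers.
#' @return An `expression_study` whose rows follow the panel order.
#' @export
restrict_to_panel <- function(study, panel) {
  stopifnot(inherits(study, "expression_study"))
  genes <- if (inherits(panel, "gene_panel")) panel$gene_ids else as.character(panel)
  present <- sum(genes %in% study$gene_ids)
  if (present < 2)
    stop("fewer than 2 panel genes present in the study: unusable study")
  out <- matrix(NA_real_, length(genes), ncol(study$values),
                dimnames = list(genes, study$sample_ids))
  hit <- intersect(genes, study$gene_ids)
  out[hit, ] <- study$values[hit, , drop = FALSE]
  expression_study(out, study$study_id, genes, study$sample_ids)
}
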