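# Gene-gene correlation machinery.
#
# All correlations are pairwise-complete Pearson correlations computed from
# sufficient statistics (pair counts, pair sums, pair sums of squares and
# cross-products), assembled with matrix products. Keeping the sufficient
# statistics around makes leave-one-out recomputation a rank-1 downdate
# instead of an O(p^2 n) rebuild per sample.

# Build the pairwise-complete sufficient statistics for a (centered) data
# matrix. Xc0: centered values with missing set to 0; O: 0/1 observed mask.
.gene_moments <- function(values) {
  O <- (!is.na(values)) * 1
  Xc <- values - rowMeans(values, na.rm = TRUE)
  Xc0 <- Xc
  Xc0[is.na(Xc0)] <- 0
  list(
    Xc0 = Xc0,
    O = O,
    N = O %*% t(O),            # pair-complete sample counts
    S = Xc0 %*% t(O),          # S[i,j]: sum of gene i over samples complete for (i,j)
    SS = (Xc0 * Xc0) %*% t(O), # SS[i,j]: sum of squares of gene i over those samples
    P = Xc0 %*% t(Xc0)         # cross-products
  )
}

# Correlation + validity from sufficient statistics. Variance numerators
# below a relative floor are treated as zero variance (pair invalid).
.moments_to_z <- function(N, S, SS, P, clip = 1 - 1e-12, min_pairs = 4) {
  varnum <- N * SS - S * S               # N^2 * pairwise variance of gene i
  covnum <- N * P - S * t(S)
  tol <- 1e-9 * N * SS
  ok_var <- varnum > tol & varnum > 0
  valid <- (N >= min_pairs) & ok_var & t(ok_var)
  diag(valid) <- FALSE
  denom <- sqrt(varnum * t(varnum))
  r <- matrix(NA_real_, nrow(N), ncol(N), dimnames = dimnames(N))
  r[valid] <- covnum[valid] / denom[valid]
  r[valid] <- pmin(pmax(r[valid], -clip), clip)
  z <- atanh(r)
  list(z = z, valid = valid)
}

.offdiag_sd <- function(z, valid) {
  v <- z[upper.tri(z) & valid]
  if (length(v) == 0) return(NA_real_)
  sqrt(mean((v - mean(v))^2))  # population SD
}

#' Fisher-z gene-gene correlation matrix of a study
#'
#' Computes, for every gene pair, the Pearson correlation over
#' pairwise-complete samples, then the Fisher z-transform `z = atanh(r)`.
#' Correlations are clipped to `+/-(1 - 1e-12)` before the transform so that
#' degenerate perfect correlations stay finite. Pairs with fewer than
#' `min_pairs` complete observations, or involving a gene with zero variance
#' over the pair's samples, are marked invalid. The sufficient statistics
#' are retained for efficient leave-one-out use (see [loo_z_matrix()]).
#'
#' @param study An `expression_study` with at least 4 samples (the Fisher-z
#'   sampling variance `1/(n-3)` is undefined below that).
#' @param min_pairs Minimum complete observations per gene pair.
#' @return An object of class `correlation_summary`: `study_id`, `gene_ids`,
#'   `z` (symmetric p x p Fisher-z matrix, `NA` where invalid), `valid`
#'   (logical matrix, diagonal excluded), `n_samples`, `sigma_s` (population
#'   SD of the defined off-diagonal z entries) and `moments`.
#' @examples
#' s <- expression_study(matrix(rnorm(50), 5, 10))
#' cs <- gene_correlations(s)
#' cs$sigma_s
#' @export
gene_correlations <- function(study, min_pairs = 4) {
  stopifnot(inherits(study, "expression_study"))
  n <- ncol(study$values)
  if (n < 4)
    stop("at least 4 samples are required (z variance 1/(n-3) undefined)")
  nz_var <- sum(apply(study$values, 1, function(x) {
    x <- x[!is.na(x)]
    length(x) >= 2 && stats::var(x) > 0
  }))
  if (nz_var < 2)
    stop("fewer than 2 genes with nonzero variance")
  mom <- .gene_moments(study$values)
  zz <- .moments_to_z(mom$N, mom$S, mom$SS, mom$P, min_pairs = min_pairs)
  structure(
    list(study_id = study$study_id,
         gene_ids = study$gene_ids,
         z = zz$z,
         valid = zz$valid,
         n_samples = n,
         sigma_s = .offdiag_sd(zz$z, zz$valid),
         moments = mom,
         min_pairs = min_pairs),
    class = "correlation_summary"
  )
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf(
    "correlation_summary '%s': %d genes, %d samples, sigma_s = %.4f\n",
    x$study_id, length(x$gene_ids), x$n_samples, x$sigma_s))
  invisible(x)
}

#' Leave-one-out Fisher-z matrix by sufficient-statistic downdating
#'
#' Removes one sample's additive contribution to the pair counts, sums,
#' sums of squares and cross-products of a [gene_correlations()] summary and
#' re-forms the correlation and z matrices for the remaining `n - 1`
#' samples. Identical (to ~1e-8) to recomputing [gene_correlations()] on
#' the study with that column deleted. If removal leaves a gene with zero
#' variance, its pairs are marked invalid rather than erroring.
#'
#' @param summary A `correlation_summary` with at least 5 samples.
#' @param sample_index Column index of the sample to remove.
#' @return List with `z` and `valid` for the leave-one-out study.
#' @export
loo_z_matrix <- function(summary, sample_index) {
  stopifnot(inherits(summary, "correlation_summary"))
  if (summary$n_samples < 5)
    stop("leave-one-out requires at least 5 samples")
  i <- as.integer(sample_index)
  if (i < 1 || i > summary$n_samples) stop("sample index out of range")
  m <- summary$moments
  o <- m$O[, i]
  x <- m$Xc0[, i]
  .moments_to_z(m$N - tcrossprod(o),
                m$S - tcrossprod(x, o),
                m$SS - tcrossprod(x * x, o),
                m$P - tcrossprod(x),
                min_pairs = summary$min_pairs)
}

#' Compendium-median reference correlation matrix
#'
#' Element-wise median over studies of the Fisher-z gene-gene correlation
#' matrices: the expected correlation structure that individual studies are
#' scored against. An entry is defined only where it is valid in at least
#' half (rounded up) of the studies; medians over an even number of values
#' take the midpoint of the central two. (Since `atanh` is strictly
#' increasing, the median of z equals the z of the median r.)
#'
#' @param summaries List of `correlation_summary` objects on a common gene
#'   panel.
#' @return An object of class `reference_correlation`: `gene_ids`,
#'   `median_z`, `valid`, `n_studies`, `sigma_med` (population SD of the
#'   defined off-diagonal entries).
#' @export
build_reference <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  stopifnot(all(vapply(summaries, inherits, TRUE, "correlation_summary")))
  genes <- summaries[[1]]$gene_ids
  for (s in summaries) {
    if (!identical(s$gene_ids, genes))
      stop("all summaries must share the same gene panel")
  }
  p <- length(genes)
  ns <- length(summaries)
  Z <- vapply(summaries, function(s) {
    z <- s$z
    z[!s$valid] <- NA_real_
    as.vector(z)
  }, numeric(p * p))
  Z <- matrix(Z, nrow = p * p, ncol = ns)
  nvalid <- rowSums(!is.na(Z))
  quorum <- ceiling(ns / 2)
  med <- rep(NA_real_, p * p)
  keep <- nvalid >= quorum & nvalid > 0
  med[keep] <- apply(Z[keep, , drop = FALSE], 1, stats::median, na.rm = TRUE)
  median_z <- matrix(med, p, p, dimnames = list(genes, genes))
  valid <- matrix(keep, p, p)
  diag(valid) <- FALSE
  median_z[!valid] <- NA_real_
  structure(
    list(gene_ids = genes,
         median_z = median_z,
         valid = valid,
         n_studies = ns,
         sigma_med = .offdiag_sd(median_z, valid)),
    class = "reference_correlation"
  )
}

#' @export
print.reference_correlation <- function(x, ...) {
  cat(sprintf(
    "reference_correlation: %d genes, median over %d studies, sigma_med = %.4f\n",
    length(x$gene_ids), x$n_studies, x$sigma_med))
  invisible(x)
}
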