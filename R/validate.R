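# Validation statistics linking SNR to statistical power and sample
# quality: the fraction of differentially expressed genes by two-sample
# t-test, leave-one-out Gaussian naive Bayes posteriors, and rank summaries
# of flagged samples.

.check_labels <- function(study, labels) {
  stopifnot(inherits(study, "expression_study"))
  labels <- as.character(labels)
  if (length(labels) != ncol(study$values))
    stop("one label is required per sample")
  labels
}

#' Fraction of differentially expressed genes
#'
#' For each gene, a two-sample two-sided pooled-variance (Student) t-test of
#' the target class against all other samples; returns the fraction of genes
#' with `p < alpha`. Genes whose pooled variance is zero (no within-group
#' variation) are excluded from the denominator. Used as a proxy for a
#' study's statistical power.
#'
#' @param study An `expression_study`.
#' @param labels Class label per sample.
#' @param target_class Label of the class tested against the rest.
#' @param alpha Significance threshold (default 0.001).
#' @return Fraction in `[0, 1]` of testable genes significant at `alpha`.
#' @export
deg_fraction <- function(study, labels, target_class, alpha = 0.001) {
  labels <- .check_labels(study, labels)
  stopifnot(alpha > 0, alpha < 1)
  in1 <- labels == as.character(target_class)
  if (sum(in1) < 2 || sum(!in1) < 2)
    stop("target class and its complement each need at least 2 samples")
  p <- deg_pvalues(study, in1)
  ok <- !is.na(p)
  if (!any(ok)) stop("no testable genes (all zero pooled variance)")
  mean(p[ok] < alpha)
}

#' Per-gene pooled-variance t-test p-values
#'
#' Vectorized two-sided Student t-test of the samples flagged by `in1`
#' against the rest, per gene, over non-missing values. Genes with fewer
#' than 2 observations in either group or zero pooled variance get `NA`.
#'
#' @param study An `expression_study`.
#' @param in1 Logical vector flagging the first group's samples.
#' @return Numeric vector of p-values, one per gene.
#' @export
deg_pvalues <- function(study, in1) {
  x <- study$values
  stopifnot(is.logical(in1), length(in1) == ncol(x))
  x1 <- x[, in1, drop = FALSE]
  x2 <- x[, !in1, drop = FALSE]
  n1 <- rowSums(!is.na(x1))
  n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE)
  m2 <- rowMeans(x2, na.rm = TRUE)
  ss1 <- rowSums((x1 - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((x2 - m2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  pval[n1 < 2 | n2 < 2 | !is.finite(tstat)] <- NA_real_
  pval
}

#' Leave-one-out naive Bayes posterior of each sample's true class
#'
#' Two-class Gaussian naive Bayes with equal (uninformative) class priors.
#' For each held-out sample, per-gene class-conditional means and variances
#' (variance floored at `var_floor`) are fit on the remaining samples,
#' per-gene log-likelihoods are summed, and the posterior probability of the
#' sample's true class is returned. Low posteriors flag samples the study's
#' own structure cannot classify — a biological proxy for bad samples.
#'
#' @param study An `expression_study` with no missing values.
#' @param labels Class label per sample; exactly 2 classes, each with at
#'   least 3 samples.
#' @param var_floor Lower bound on fitted per-gene variances.
#' @return Named numeric vector of true-class posteriors, one per sample.
#' @export
nb_loo_posteriors <- function(study, labels, var_floor = 1e-6) {
  labels <- .check_labels(study, labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("exactly 2 classes are required")
  if (any(table(labels) < 3)) stop("each class needs at least 3 samples")
  x <- study$values
  n <- ncol(x)
  post <- numeric(n)
  for (i in seq_len(n)) {
    xt <- x[, -i, drop = FALSE]
    lt <- labels[-i]
    loglik <- vapply(classes, function(cl) {
      xc <- xt[, lt == cl, drop = FALSE]
      mu <- rowMeans(xc)
      v <- pmax(apply(xc, 1, stats::var), var_floor)
      sum(stats::dnorm(x[, i], mu, sqrt(v), log = TRUE))
    }, numeric(1))
    # equal priors; posterior of the sample's own class via log-sum-exp
    loglik <- loglik - max(loglik)
    post[i] <- exp(loglik[classes == labels[i]]) / sum(exp(loglik))
  }
  stats::setNames(post, study$sample_ids)
}

#' Mean posterior rank of quality-flagged samples
#'
#' Ranks the classifier posteriors ascending (rank 1 = least classifiable)
#' with average ranks on ties, and returns the mean rank of the `k` samples
#' with the lowest quality scores. A quality measure that flags genuinely
#' bad samples yields a mean rank well below `(n + 1) / 2`.
#'
#' @param posteriors Per-sample posterior probabilities.
#' @param quality_scores Per-sample quality scores (lower = worse).
#' @param k Number of worst-quality samples to summarize.
#' @return Mean posterior rank of the flagged samples.
#' @export
mean_rank_of_flagged <- function(posteriors, quality_scores, k) {
  stopifnot(length(posteriors) == length(quality_scores),
            k >= 1, k <= length(posteriors))
  r <- rank(posteriors, ties.method = "average")
  flagged <- order(quality_scores)[seq_len(k)]
  mean(r[flagged])
}

#' Noise-degradation experiment: study SNR versus %DEG
#'
#' Takes one labeled study from a simulated compendium, builds the median
#' reference from the remaining (clean) studies, and for each noise level in
#' `noise_grid` and each replicate injects Gaussian noise, then records the
#' raw study SNR and the fraction of differentially expressed genes. Both
#' should degrade together as noise grows.
#'
#' @param compendium A `simulated_compendium` with `n_classes >= 2`.
#' @param noise_grid Noise SDs to scan.
#' @param alpha Significance threshold for [deg_fraction()].
#' @param seed Integer seed.
#' @param n_reps Replicates per noise level.
#' @param study_index Which study of the compendium to degrade.
#' @return Data frame with columns `sigma`, `rep`, `snr_raw`,
#'   `deg_fraction`.
#' @export
snr_vs_deg_experiment <- function(compendium, noise_grid = c(0, 0.5, 1, 2, 4),
                                  alpha = 0.001, seed = 0, n_reps = 20,
                                  study_index = 1) {
  stopifnot(inherits(compendium, "simulated_compendium"))
  labels <- compendium$labels[[study_index]]
  if (length(unique(labels)) < 2)
    stop("the degraded study needs class labels (n_classes >= 2)")
  ref <- build_reference(lapply(
    compendium$studies[-study_index], gene_correlations))
  study <- compendium$studies[[study_index]]
  grid <- expand.grid(rep = seq_len(n_reps), sigma = noise_grid)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    sg <- grid$sigma[g]
    noisy <- inject_noise(study, sg, seed = seed + 7919L * g)
    snr <- study_snr(gene_correlations(noisy), ref, disattenuate = FALSE)
    data.frame(sigma = sg, rep = grid$rep[g],
               snr_raw = snr$snr_raw,
               deg_fraction = deg_fraction(noisy, labels, 2, alpha = alpha))
  })
  do.call(rbind, res)
}
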