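# Study- and sample-level signal-to-noise scores.
#
# A study's SNR is the Pearson correlation between its Fisher-z gene-gene
# correlations and the compendium-median reference, over the off-diagonal
# pairs jointly defined in both (each unordered pair counted once). The
# score is optionally disattenuated for the sampling error of z, which for
# normal data has variance 1/(n - 3). A sample's score is the drop in a
# modified study SNR when it is removed.

# Joint off-diagonal mask, each unordered pair once.
.joint_pairs <- function(summary_valid, reference_valid) {
  upper.tri(summary_valid) & summary_valid & reference_valid
}

#' Disattenuate a study SNR for the number of samples
#'
#' Fisher-z correlations estimated from `n` samples carry sampling error
#' with variance `v = 1/(n - 3)` (normal data). That error attenuates the
#' correlation between a study's z values and the reference. If the
#' observed spread `sigma_s` of the study's z values exceeds what sampling
#' error alone would produce (`sigma_s^2 > v`), the correlation attainable
#' with infinitely many samples is estimated as
#' `snr_raw / sqrt(1 - v / sigma_s^2)`, clamped to `[-1, 1]`. The reference,
#' a median over many studies, is treated as error-free. If
#' `sigma_s^2 <= v`, all observed spread is attributable to sampling error
#' and the disattenuated value is undefined (`NA` with a warning).
#'
#' @param snr_raw Raw study SNR (a correlation in `[-1, 1]`).
#' @param sigma_s Standard deviation of the study's defined off-diagonal z
#'   entries.
#' @param n_samples Number of samples in the study (>= 4).
#' @return Disattenuated SNR, or `NA` when undefined.
#' @examples
#' disattenuate_value(0.5, sqrt(2 / (20 - 3)), 20)  # 0.5 / sqrt(0.5)
#' @export
disattenuate_value <- function(snr_raw, sigma_s, n_samples) {
  if (n_samples < 4) stop("disattenuation requires at least 4 samples")
  v <- 1 / (n_samples - 3)
  if (!is.finite(sigma_s) || sigma_s^2 <= v) {
    warning("observed z spread is attributable to sampling error alone; ",
            "disattenuated SNR undefined")
    return(NA_real_)
  }
  q <- snr_raw / sqrt(1 - v / sigma_s^2)
  min(max(q, -1), 1)
}

#' Study signal-to-noise ratio
#'
#' Correlates the study's Fisher-z gene-gene correlations with the
#' reference's median z values over the jointly defined off-diagonal pairs.
#' The spread `sigma_s` entering the disattenuation is computed over those
#' same jointly defined pairs.
#'
#' @param summary A `correlation_summary` from [gene_correlations()].
#' @param reference A `reference_correlation` on the same gene panel.
#' @param disattenuate Apply the sample-count correction (default `TRUE`).
#' @param min_joint_pairs Minimum number of jointly defined pairs (default
#'   100) below which the overlap is considered unusable.
#' @return An object of class `study_snr`: `study_id`, `snr_raw`,
#'   `snr_disattenuated` (`NA` when not requested or undefined),
#'   `n_samples`, `n_pairs_used`, `sigma_s`.
#' @export
study_snr <- function(summary, reference, disattenuate = TRUE,
                      min_joint_pairs = 100) {
  stopifnot(inherits(summary, "correlation_summary"),
            inherits(reference, "reference_correlation"))
  if (!identical(summary$gene_ids, reference$gene_ids))
    stop("summary and reference are on different gene panels")
  joint <- .joint_pairs(summary$valid, reference$valid)
  n_pairs <- sum(joint)
  if (n_pairs < min_joint_pairs)
    stop(sprintf("only %d jointly defined pairs (< %d): unusable overlap",
                 n_pairs, min_joint_pairs))
  x <- summary$z[joint]
  y <- reference$median_z[joint]
  snr_raw <- stats::cor(x, y)
  sigma_s <- sqrt(mean((x - mean(x))^2))
  snr_dis <- NA_real_
  if (disattenuate)
    snr_dis <- disattenuate_value(snr_raw, sigma_s, summary$n_samples)
  structure(
    list(study_id = summary$study_id,
         snr_raw = snr_raw,
         snr_disattenuated = snr_dis,
         n_samples = summary$n_samples,
         n_pairs_used = n_pairs,
         sigma_s = sigma_s),
    class = "study_snr"
  )
}

#' @export
print.study_snr <- function(x, ...) {
  cat(sprintf(
    "study_snr '%s': raw %.4f, disattenuated %s (n = %d, %d pairs)\n",
    x$study_id, x$snr_raw,
    ifelse(is.na(x$snr_disattenuated), "NA",
           sprintf("%.4f", x$snr_disattenuated)),
    x$n_samples, x$n_pairs_used))
  invisible(x)
}

#' Modified study SNR with a fixed spread denominator
#'
#' The leave-one-out comparison uses a modified SNR: the mean-centered
#' cross-product between the (leave-one-out) z values and the reference over
#' jointly defined off-diagonal pairs, divided by `sigma_med * sigma_full`,
#' where `sigma_full` is the z spread of the *original* study with all
#' samples. Fixing the denominator prevents problematic samples, which can
#' inflate the study's own spread more than the cross-product, from fooling
#' the score. When the z values equal the full study's and `sigma_full` is
#' that study's spread, this reduces to the raw study SNR.
#'
#' @param z_loo List with `z` and `valid` (as returned by [loo_z_matrix()]),
#'   or a plain z matrix (all finite entries treated as valid).
#' @param reference A `reference_correlation`.
#' @param sigma_full Positive spread of the full study's z values.
#' @return The modified SNR (dimensionless; may exceed 1 in magnitude).
#' @export
modified_snr <- function(z_loo, reference, sigma_full) {
  stopifnot(inherits(reference, "reference_correlation"))
  if (!is.finite(sigma_full) || sigma_full <= 0)
    stop("sigma_full must be positive")
  if (is.matrix(z_loo)) z_loo <- list(z = z_loo, valid = is.finite(z_loo))
  joint <- .joint_pairs(z_loo$valid, reference$valid)
  x <- z_loo$z[joint]
  y <- reference$median_z[joint]
  sigma_med <- sqrt(mean((y - mean(y))^2))
  mean((x - mean(x)) * (y - mean(y))) / (sigma_med * sigma_full)
}

#' Per-sample signal-to-noise scores
#'
#' Each sample is scored by the change in the modified study SNR when it is
#' removed: `delta_i = snr(full) - snr(without i)`, computed via
#' sufficient-statistic downdating ([loo_z_matrix()]). Deltas are centered
#' by their median and divided by their median absolute deviation (no
#' consistency constant), so scores are positive for better-than-average
#' samples and negative for worse-than-average samples, with median 0 and
#' MAD 1 by construction.
#'
#' @param study An `expression_study` with at least 5 samples, or a
#'   precomputed `correlation_summary`.
#' @param reference A `reference_correlation` on the same gene panel.
#' @return An object of class `sample_snr_set`: `study_id`, `sample_ids`,
#'   `delta`, `normalized`, `center` (median of deltas), `scale` (MAD of
#'   deltas). If the MAD is 0, normalized scores are `NA` with a warning.
#' @export
sample_snr <- function(study, reference) {
  stopifnot(inherits(reference, "reference_correlation"))
  if (inherits(study, "expression_study")) {
    sample_ids <- study$sample_ids
    if (ncol(study$values) < 5)
      stop("sample scoring requires at least 5 samples")
    summary <- gene_correlations(study)
  } else if (inherits(study, "correlation_summary")) {
    summary <- study
    sample_ids <- colnames(summary$moments$Xc0)
    if (is.null(sample_ids))
      sample_ids <- paste0("sample_", seq_len(summary$n_samples))
    if (summary$n_samples < 5)
      stop("sample scoring requires at least 5 samples")
  } else {
    stop("'study' must be an expression_study or correlation_summary")
  }
  if (!identical(summary$gene_ids, reference$gene_ids))
    stop("study and reference are on different gene panels")
  joint <- .joint_pairs(summary$valid, reference$valid)
  x <- summary$z[joint]
  sigma_full <- sqrt(mean((x - mean(x))^2))
  snr_full <- modified_snr(list(z = summary$z, valid = summary$valid),
                           reference, sigma_full)
  n <- summary$n_samples
  delta <- vapply(seq_len(n), function(i) {
    snr_full - modified_snr(loo_z_matrix(summary, i), reference, sigma_full)
  }, numeric(1))
  center <- stats::median(delta)
  scale <- stats::mad(delta, constant = 1)
  if (scale > 0) {
    normalized <- (delta - center) / scale
  } else {
    warning("MAD of sample deltas is zero; normalized scores undefined")
    normalized <- rep(NA_real_, n)
  }
  structure(
    list(study_id = summary$study_id,
         sample_ids = sample_ids,
         delta = stats::setNames(delta, sample_ids),
         normalized = stats::setNames(normalized, sample_ids),
         center = center,
         scale = scale),
    class = "sample_snr_set"
  )
}

#' @export
print.sample_snr_set <- function(x, ...) {
  cat(sprintf("sample_snr_set '%s': %d samples, delta median %.3g, MAD %.3g\n",
              x$study_id, length(x$delta), x$center, x$scale))
  worst <- utils::head(order(x$normalized), 3)
  cat("  lowest normalized scores:",
      paste(sprintf("%s (%.2f)", x$sample_ids[worst], x$normalized[worst]),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.sample_snr_set <- function(x, ...) {
  data.frame(sample_id = x$sample_ids,
             delta = unname(x$delta),
             normalized = unname(x$normalized),
             stringsAsFactors = FALSE)
}
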