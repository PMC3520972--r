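# Synthetic compendium generator.
#
# Real expression compendia show a shared gene-gene correlation structure
# across studies: sets of genes are similarly correlated in study after
# study. The generator realizes this with a latent-factor model: one global
# p x f loading matrix is shared by all studies, each sample gets standard
# normal factor scores, and study-specific measurement noise is added on
# top. Multiple biological classes are emulated by shifting a random subset
# of factor means per class.

#' Simulate a compendium of studies sharing correlation structure
#'
#' Draws one global loading matrix `L` (`p` genes x `f` factors, standard
#' normal entries). Each sample's expression is `L %*% scores + noise`,
#' where `scores` are standard normal per sample and noise is i.i.d.
#' `N(0, noise_sigma^2)` per gene. With `n_classes > 1`, each class beyond
#' the first shifts a random half of the factors by `class_shift`; samples
#' are assigned to classes in near-equal numbers.
#'
#' @param p Number of genes (>= 2 * f).
#' @param f Number of latent factors.
#' @param n_studies Number of studies in the compendium.
#' @param samples_per_study Samples per study (>= 5); scalar or vector of
#'   length `n_studies`.
#' @param noise_sigma Per-gene measurement noise SD.
#' @param n_classes Number of biological classes per study.
#' @param class_shift Mean shift applied to the affected factors.
#' @param seed Integer seed; identical seed and parameters give bit-identical
#'   output.
#' @return An object of class `simulated_compendium`: `loading_matrix`,
#'   `studies` (list of `expression_study`), `labels` (list of integer class
#'   labels per study), `class_factors` (list, per class, of shifted factor
#'   indices), `noise_sigma`, `seed`.
#' @examples
#' comp <- simulate_compendium(p = 50, f = 5, n_studies = 2,
#'                             samples_per_study = 10, seed = 1)
#' comp$studies[[1]]
#' @export
simulate_compendium <- function(p = 200, f = 10, n_studies = 20,
                                samples_per_study = 50, noise_sigma = 1,
                                n_classes = 1, class_shift = 2, seed = 0) {
  if (p < 2 * f) stop("p must be at least 2 * f")
  ns <- rep_len(samples_per_study, n_studies)
  if (any(ns < 5)) stop("samples_per_study must be at least 5")
  if (n_classes < 1) stop("n_classes must be >= 1")
  set.seed(seed)
  L <- matrix(stats::rnorm(p * f), p, f)
  gene_ids <- sprintf("g%04d", seq_len(p))
  class_factors <- vector("list", n_classes)
  if (n_classes > 1) {
    for (k in seq(2, n_classes))
      class_factors[[k]] <- sort(sample.int(f, max(1L, f %/% 2)))
  }
  studies <- vector("list", n_studies)
  labels <- vector("list", n_studies)
  for (s in seq_len(n_studies)) {
    n <- ns[s]
    lab <- sample(rep_len(seq_len(n_classes), n))
    scores <- matrix(stats::rnorm(f * n), f, n)
    for (k in seq_len(n_classes)) {
      if (k > 1 && any(lab == k))
        scores[class_factors[[k]], lab == k] <-
          scores[class_factors[[k]], lab == k] + class_shift
    }
    X <- L %*% scores + matrix(stats::rnorm(p * n, sd = noise_sigma), p, n)
    sid <- sprintf("study%02d", s)
    studies[[s]] <- expression_study(
      X, sid, gene_ids, sprintf("%s_s%03d", sid, seq_len(n)))
    labels[[s]] <- lab
  }
  structure(
    list(loading_matrix = L,
         studies = studies,
         labels = labels,
         class_factors = class_factors,
         noise_sigma = noise_sigma,
         seed = seed),
    class = "simulated_compendium"
  )
}

#' @export
print.simulated_compendium <- function(x, ...) {
  cat(sprintf(
    "simulated_compendium: %d studies, %d genes, noise sigma %.2f, seed %d\n",
    length(x$studies), nrow(x$loading_matrix), x$noise_sigma, x$seed))
  invisible(x)
}

#' Correlation matrix implied by a loading matrix
#'
#' The population gene-gene correlation of the factor model
#' `x = L %*% scores + noise` is the correlation version of
#' `L %*% t(L) + noise_sigma^2 * I`.
#'
#' @param loading_matrix The p x f loading matrix.
#' @param noise_sigma Noise SD.
#' @return p x p correlation matrix.
#' @export
implied_correlation <- function(loading_matrix, noise_sigma = 0) {
  cv <- tcrossprod(loading_matrix)
  diag(cv) <- diag(cv) + noise_sigma^2
  stats::cov2cor(cv)
}

#' Add Gaussian noise to every measurement
#'
#' Adds i.i.d. `N(0, sigma^2)` to every non-missing cell. `sigma = 0`
#' returns an identical copy.
#'
#' @param study An `expression_study`.
#' @param sigma Noise SD (>= 0).
#' @param seed Integer seed.
#' @return The noisy `expression_study`.
#' @export
inject_noise <- function(study, sigma, seed = 0) {
  stopifnot(inherits(study, "expression_study"), sigma >= 0)
  if (sigma == 0) return(study)
  set.seed(seed)
  v <- study$values
  obs <- !is.na(v)
  v[obs] <- v[obs] + stats::rnorm(sum(obs), sd = sigma)
  expression_study(v, study$study_id, study$gene_ids, study$sample_ids)
}

#' Replace one sample by structure-free noise
#'
#' Overwrites one column with i.i.d. draws matching the study's global mean
#' and standard deviation but carrying none of the gene-gene structure: a
#' fixture for a sample that is pure technical noise.
#'
#' @param study An `expression_study`.
#' @param sample_index Column to corrupt.
#' @param seed Integer seed.
#' @return The corrupted `expression_study`.
#' @export
corrupt_sample <- function(study, sample_index, seed = 0) {
  stopifnot(inherits(study, "expression_study"))
  i <- as.integer(sample_index)
  if (is.na(i) || i < 1 || i > ncol(study$values))
    stop("sample index out of range")
  set.seed(seed)
  v <- study$values
  m <- mean(v, na.rm = TRUE)
  s <- stats::sd(as.vector(v), na.rm = TRUE)
  v[, i] <- stats::rnorm(nrow(v), mean = m, sd = s)
  expression_study(v, study$study_id, study$gene_ids, study$sample_ids)
}

#' Mix samples from two groups into one study
#'
#' Draws `n_a` samples without replacement from `group_a` and `n_b` from
#' `group_b` (sharing the same gene panel), concatenates them and shuffles
#' the column order deterministically by `seed`.
#'
#' @param group_a,group_b `expression_study` objects on the same gene panel.
#' @param n_a,n_b Numbers of samples to draw from each group.
#' @param seed Integer seed.
#' @return An `expression_study` with `n_a + n_b` columns and an attribute
#'   `group` (character vector "a"/"b" per column, in output order).
#' @export
mix_groups <- function(group_a, group_b, n_a, n_b, seed = 0) {
  stopifnot(inherits(group_a, "expression_study"),
            inherits(group_b, "expression_study"))
  if (!identical(group_a$gene_ids, group_b$gene_ids))
    stop("groups must share the same gene panel")
  if (n_a > ncol(group_a$values) || n_b > ncol(group_b$values))
    stop("requested more samples than a group contains")
  set.seed(seed)
  ia <- if (n_a > 0) sort(sample.int(ncol(group_a$values), n_a)) else integer(0)
  ib <- if (n_b > 0) sort(sample.int(ncol(group_b$values), n_b)) else integer(0)
  v <- cbind(group_a$values[, ia, drop = FALSE],
             group_b$values[, ib, drop = FALSE])
  grp <- c(rep("a", n_a), rep("b", n_b))
  ord <- sample.int(ncol(v))
  v <- v[, ord, drop = FALSE]
  grp <- grp[ord]
  colnames(v) <- make.unique(colnames(v), sep = "_dup")
  out <- expression_study(v, paste0(group_a$study_id, "_mix"),
                          group_a$gene_ids, colnames(v))
  attr(out, "group") <- grp
  out
}
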