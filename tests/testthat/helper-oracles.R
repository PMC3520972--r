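# Brute-force oracles and small fixture builders shared across tests.
# The oracles are deliberately naive (loops, two-pass formulas, rebuilds
# from scratch) and independent of the package's sufficient-statistic path.

random_study <- function(p, n, seed, missing_frac = 0, study_id = "rnd") {
  set.seed(seed)
  m <- matrix(rnorm(p * n), p, n)
  if (missing_frac > 0)
    m[runif(p * n) < missing_frac] <- NA_real_
  expression_study(m, study_id)
}

# Textbook two-pass pairwise-complete Pearson correlation + Fisher z.
naive_z_matrix <- function(values, min_pairs = 4, clip = 1 - 1e-12) {
  p <- nrow(values)
  z <- matrix(NA_real_, p, p)
  valid <- matrix(FALSE, p, p)
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      ok <- !is.na(values[i, ]) & !is.na(values[j, ])
      if (sum(ok) < min_pairs) next
      x <- values[i, ok]; y <- values[j, ok]
      if (var(x) == 0 || var(y) == 0) next
      r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      r <- min(max(r, -clip), clip)
      z[i, j] <- z[j, i] <- atanh(r)
      valid[i, j] <- valid[j, i] <- TRUE
    }
  }
  list(z = z, valid = valid)
}

# Sample deltas by rebuilding every leave-one-out study from scratch.
brute_force_sample_deltas <- function(study, reference) {
  cs <- gene_correlations(study)
  joint <- upper.tri(cs$valid) & cs$valid & reference$valid
  x <- cs$z[joint]
  sigma_full <- sqrt(mean((x - mean(x))^2))
  snr_full <- modified_snr(list(z = cs$z, valid = cs$valid),
                           reference, sigma_full)
  n <- ncol(study$values)
  vapply(seq_len(n), function(i) {
    loo <- expression_study(study$values[, -i, drop = FALSE],
                            study$study_id, study$gene_ids,
                            study$sample_ids[-i])
    cl <- gene_correlations(loo)
    snr_full - modified_snr(list(z = cl$z, valid = cl$valid),
                            reference, sigma_full)
  }, numeric(1))
}

# Small compendium + reference used by several tests.
small_reference <- function(p = 60, f = 6, n_studies = 6, n = 25, seed = 42) {
  comp <- simulate_compendium(p = p, f = f, n_studies = n_studies,
                              samples_per_study = n, noise_sigma = 1,
                              seed = seed)
  list(comp = comp,
       ref = build_reference(lapply(comp$studies, gene_correlations)))
}
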