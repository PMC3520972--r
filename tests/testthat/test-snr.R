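test_that("a study correlated against itself scores 1, against its negation -1", {
  cs <- gene_correlations(random_study(20, 12, 8))
  ref <- build_reference(list(cs))
  expect_equal(study_snr(cs, ref, disattenuate = FALSE)$snr_raw, 1.0)

  neg <- cs
  neg$z <- -neg$z
  expect_equal(study_snr(neg, ref, disattenuate = FALSE)$snr_raw, -1.0)
})

test_that("study SNR is symmetric in which matrix plays the reference", {
  a <- gene_correlations(random_study(25, 15, 1, study_id = "a"))
  b <- gene_correlations(random_study(25, 15, 2, study_id = "b"))
  ab <- study_snr(a, build_reference(list(b)), disattenuate = FALSE)$snr_raw
  ba <- study_snr(b, build_reference(list(a)), disattenuate = FALSE)$snr_raw
  expect_equal(ab, ba, tolerance = 1e-12)
})

test_that("too little overlap with the reference is an error", {
  cs <- gene_correlations(random_study(10, 12, 3))  # 45 pairs < 100
  ref <- build_reference(list(cs))
  expect_error(study_snr(cs, ref), "unusable overlap")
})

test_that("disattenuation follows the closed form and its guards", {
  # v -> 0: unchanged
  expect_equal(disattenuate_value(0.62, 10, 1e6), 0.62, tolerance = 1e-5)
  # sigma^2 = 2v: q / sqrt(1/2)
  n <- 20; v <- 1 / (n - 3)
  expect_equal(disattenuate_value(0.5, sqrt(2 * v), n), 0.5 / sqrt(0.5))
  # spread fully explained by sampling error: undefined
  expect_warning(out <- disattenuate_value(0.5, sqrt(v), n), "undefined")
  expect_true(is.na(out))
  expect_error(disattenuate_value(0.5, 1, 3), "at least 4")
  # clamped into [-1, 1]
  expect_equal(disattenuate_value(0.99, sqrt(1.05 * v), n), 1)
})

test_that("disattenuated magnitude is never below the raw magnitude", {
  sr <- small_reference()
  for (s in 1:3) {
    sn <- study_snr(gene_correlations(sr$comp$studies[[s]]), sr$ref)
    if (!is.na(sn$snr_disattenuated))
      expect_gte(abs(sn$snr_disattenuated), abs(sn$snr_raw))
    expect_lte(abs(sn$snr_raw), 1)
    expect_lte(sn$n_pairs_used, choose(length(sr$ref$gene_ids), 2))
  }
})

test_that("raw SNR ignores sample duplication; disattenuation sees only n", {
  sr <- small_reference()
  st <- sr$comp$studies[[1]]
  dup <- expression_study(cbind(st$values, st$values), "dup", st$gene_ids,
                          paste0("s", seq_len(2 * ncol(st$values))))
  a <- study_snr(gene_correlations(st), sr$ref)
  b <- study_snr(gene_correlations(dup), sr$ref)
  expect_equal(b$snr_raw, a$snr_raw, tolerance = 1e-10)
  expect_equal(b$sigma_s, a$sigma_s, tolerance = 1e-10)
  # same raw score and spread, more samples -> correction can only shrink
  expect_false(isTRUE(all.equal(a$n_samples, b$n_samples)))
  expect_equal(b$snr_disattenuated,
               disattenuate_value(a$snr_raw, a$sigma_s, 2 * a$n_samples),
               tolerance = 1e-10)
})

test_that("leave-one-out downdating matches rebuilding from scratch", {
  for (seed in 1:3) {
    st <- random_study(30, 15, seed + 100,
                       missing_frac = ifelse(seed == 3, 0.1, 0))
    cs <- gene_correlations(st)
    for (i in c(1, 7, 15)) {
      loo <- loo_z_matrix(cs, i)
      rebuilt <- gene_correlations(
        expression_study(st$values[, -i, drop = FALSE], "loo", st$gene_ids))
      expect_equal(loo$valid, rebuilt$valid, ignore_attr = TRUE)
      expect_lt(max(abs(loo$z[loo$valid] - rebuilt$z[rebuilt$valid])), 1e-8)
    }
  }
})

test_that("leave-one-out marks pairs invalid when variance collapses", {
  # gene 'a' varies only through sample 5; removing it kills the variance
  v <- rbind(a = c(1, 1, 1, 1, 2),
             b = c(1, 2, 3, 4, 5),
             c = c(2, 1, 4, 3, 5),
             d = c(5, 3, 1, 2, 4))
  cs <- gene_correlations(expression_study(v))
  loo <- loo_z_matrix(cs, 5)
  expect_false(any(loo$valid[1, ]))
  expect_true(loo$valid[2, 3])
})

test_that("modified SNR reduces to the raw SNR at the full study", {
  sr <- small_reference()
  cs <- gene_correlations(sr$comp$studies[[2]])
  sn <- study_snr(cs, sr$ref, disattenuate = FALSE)
  m <- modified_snr(list(z = cs$z, valid = cs$valid), sr$ref, sn$sigma_s)
  expect_equal(m, sn$snr_raw, tolerance = 1e-12)
  # halving the denominator doubles the statistic: it may exceed 1
  expect_equal(modified_snr(list(z = cs$z, valid = cs$valid),
                            sr$ref, sn$sigma_s / 2),
               2 * sn$snr_raw, tolerance = 1e-12)
  expect_error(modified_snr(cs$z, sr$ref, 0), "positive")
})

test_that("sample deltas match the brute-force rebuild and are MAD-normalized", {
  sr <- small_reference(p = 30, f = 4, n_studies = 5, n = 15, seed = 7)
  st <- sr$comp$studies[[1]]
  ss <- sample_snr(st, sr$ref)
  expect_equal(unname(ss$delta),
               brute_force_sample_deltas(st, sr$ref),
               tolerance = 1e-8)
  expect_equal(median(ss$normalized), 0)
  expect_equal(mad(ss$normalized, constant = 1), 1)
  expect_equal(ss$center, median(ss$delta))
})

test_that("sample scoring refuses tiny studies and degenerate spreads", {
  sr <- small_reference(p = 30, f = 4, n_studies = 4, n = 10, seed = 19)
  tiny <- expression_study(sr$comp$studies[[1]]$values[, 1:4], "tiny",
                           sr$comp$studies[[1]]$gene_ids)
  expect_error(sample_snr(tiny, sr$ref), "at least 5")
})

test_that("a structure-free sample gets the lowest score", {
  sr <- small_reference(p = 80, f = 8, n_studies = 6, n = 30, seed = 23)
  st <- corrupt_sample(sr$comp$studies[[1]], 11, seed = 5)
  ss <- sample_snr(st, sr$ref)
  expect_equal(unname(which.min(ss$normalized)), 11)
  expect_lt(ss$normalized[11], 0)
})
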