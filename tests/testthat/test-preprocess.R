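test_that("log transform triggers only on linear-scale matrices", {
  m <- matrix(c(1, 5, 14.2, 8), 2, 2)
  out <- maybe_log_transform(m)
  expect_false(out$applied)
  expect_identical(out$values, m)

  big <- matrix(c(20000, 1023, 500, 3), 2, 2)
  out <- maybe_log_transform(big)
  expect_true(out$applied)
  expect_equal(out$values[2, 1], 10)  # log2(1023 + 1)
  # negatives clipped to 0 before the transform
  neg <- matrix(c(-2, 40000, 7, 7), 2, 2)
  expect_equal(maybe_log_transform(neg)$values[1, 1], 0)

  expect_error(maybe_log_transform(matrix(NA_real_, 2, 2)), "non-missing")
})

test_that("median polish decomposes additive tables exactly", {
  r <- c(1, 4, -2); c_ <- c(0, 3, 5, 1)
  m <- outer(r, c_, `+`) + 10
  mp <- median_polish(m)
  expect_equal(max(abs(mp$residuals)), 0)
  fit <- mp$overall + outer(mp$row_effects, mp$col_effects, `+`)
  expect_equal(fit + mp$residuals, m, ignore_attr = TRUE)

  one <- median_polish(matrix(5, 1, 1))
  expect_equal(one$overall, 5)
  expect_equal(max(abs(one$residuals)), 0)
})

test_that("median polish matches the hand-iterated 2x2 example", {
  mp <- median_polish(matrix(c(1, 3, 2, 5), 2, 2))
  expect_equal(mp$residuals,
               matrix(c(0.25, -0.25, -0.25, 0.25), 2, 2),
               ignore_attr = TRUE)
})

test_that("median polish residuals ignore row/column shifts", {
  # median decompositions are unique only up to the sweep tolerance, so the
  # residuals are compared at the eps used for the polish
  set.seed(3)
  m <- matrix(rnorm(45), 5, 9)
  eps <- 0.01
  base <- median_polish(m, eps = eps, max_iter = 50)$residuals
  m2 <- m; m2[3, ] <- m2[3, ] + 7; m2[, 5] <- m2[, 5] - 2.5
  shifted <- median_polish(m2, eps = eps, max_iter = 50)$residuals
  expect_lt(max(abs(base - shifted)), eps)
})

test_that("downstream correlations are unchanged by re-adding row effects", {
  set.seed(4)
  m <- matrix(rnorm(120), 8, 15)
  mp <- median_polish(m)
  resid_only <- expression_study(mp$residuals, "a")
  with_rows <- expression_study(
    mp$residuals + mp$overall + matrix(mp$row_effects, 8, 15), "b")
  za <- gene_correlations(resid_only)$z
  zb <- gene_correlations(with_rows)$z
  expect_equal(za, zb, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("missing-probe filter uses a strict threshold", {
  mm <- matrix(rnorm(16 * 4), 4, 16)
  mm[1, 1:5] <- NA   # 31.25% -> removed
  mm[2, 1:4] <- NA   # exactly 25% -> kept
  mm[3, ] <- rnorm(16)  # 0% -> kept
  rownames(mm) <- paste0("p", 1:4)
  kept <- filter_missing_probes(mm, 0.25)
  expect_identical(rownames(kept), c("p2", "p3", "p4"))

  all_na <- matrix(NA_real_, 2, 4)
  expect_error(filter_missing_probes(all_na), "empty study")
})

test_that("probe collapsing takes per-sample medians and drops ambiguity", {
  vals <- rbind(p1 = c(1, 10), p2 = c(3, 20), p3 = c(9, 30),
                p4 = c(5, 5), p5 = c(7, 7), p6 = c(2, 2))
  colnames(vals) <- c("s1", "s2")
  map <- data.frame(probe = c("p1", "p2", "p3", "p4", "p5", "p5", "p6"),
                    gene = c("gA", "gA", "gA", "gB", "gC", "gD", "gE"))
  # p5 maps to two genes -> dropped; p6 has no conflict
  st <- collapse_probes_to_genes(vals, map)
  expect_setequal(st$gene_ids, c("gA", "gB", "gE"))
  expect_equal(unname(st$values["gA", ]), c(3, 20))  # median of 1,3,9 / 10,20,30
  expect_equal(unname(st$values["gB", ]), c(5, 5))   # single probe passthrough
  expect_error(collapse_probes_to_genes(vals, map[0, ]), "empty")
})

test_that("collapsing uses non-missing probes per sample", {
  vals <- rbind(p1 = c(1, NA), p2 = c(3, NA))
  colnames(vals) <- c("s1", "s2")
  map <- data.frame(probe = c("p1", "p2"), gene = c("g", "g"))
  st <- collapse_probes_to_genes(vals, map)
  expect_equal(unname(st$values["g", 1]), 2)
  expect_true(is.na(st$values["g", 2]))
})

test_that("gene panel ranks by platform count with identifier tie-break", {
  sets <- list(c("gA", "gB", "gC"), c("gA", "gB"), c("gA", "gD"),
               c("gA", "gB"), c("gA"))
  panel <- select_gene_panel(sets, k = 1)
  expect_identical(panel$gene_ids, "gA")  # 5 platforms beats 3

  tie <- list(c("gZ", "gB"), c("gZ", "gB"), c("gQ"))
  expect_identical(select_gene_panel(tie, k = 1)$gene_ids, "gB")

  expect_warning(capped <- select_gene_panel(sets, k = 10), "smaller")
  expect_length(capped$gene_ids, 4)
})

test_that("panel restriction aligns, records absent genes, and errors on disjoint sets", {
  st <- expression_study(matrix(1:6, 3, 2,
                                dimnames = list(c("g2", "g1", "g3"),
                                                c("s1", "s2"))))
  panel <- select_gene_panel(list(c("g1", "g2", "g4")), k = 3)
  out <- restrict_to_panel(st, panel)
  expect_identical(out$gene_ids, panel$gene_ids)
  expect_true(all(is.na(out$values["g4", ])))
  expect_equal(out$values["g1", ], st$values["g1", ])

  other <- expression_study(matrix(1:4, 2, 2,
                                   dimnames = list(c("x1", "x2"),
                                                   c("s1", "s2"))))
  expect_error(restrict_to_panel(other, panel), "unusable")
})

test_that("filter -> collapse -> restrict is idempotent on its own output", {
  set.seed(9)
  vals <- matrix(rnorm(80), 8, 10,
                 dimnames = list(paste0("p", 1:8), paste0("s", 1:10)))
  vals[1, 1:4] <- NA
  map <- data.frame(probe = paste0("p", 1:8),
                    gene = paste0("g", c(1, 1, 2, 3, 4, 5, 6, 6)))
  run <- function(v) {
    st <- collapse_probes_to_genes(filter_missing_probes(v), map)
    restrict_to_panel(st, select_gene_panel(list(st$gene_ids),
                                            k = length(st$gene_ids)))
  }
  once <- run(vals)
  map2 <- data.frame(probe = once$gene_ids, gene = once$gene_ids)
  st2 <- collapse_probes_to_genes(filter_missing_probes(once$values), map2)
  twice <- restrict_to_panel(
    st2, select_gene_panel(list(st2$gene_ids), k = length(st2$gene_ids)))
  expect_equal(twice$values, once$values, ignore_attr = TRUE)
  expect_identical(twice$gene_ids, once$gene_ids)
})
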