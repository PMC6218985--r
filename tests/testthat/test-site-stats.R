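test_that("exact Wilcoxon matches full rank-assignment enumeration", {
  # all mutated values above all wild-type: 1 of C(7,3)=35 assignments
  p <- wilcoxon_site_test(c(0.9, 0.8, 0.85), c(0.1, 0.2, 0.15, 0.05))
  expect_equal(unname(p["p_greater"]), 1 / 35, tolerance = 1e-12)
  # tie-free cases agree exactly with the enumeration oracle
  set.seed(4)
  for (i in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:8, 1)
    x <- runif(n1); y <- runif(n2)
    expect_equal(unname(wilcoxon_site_test(x, y)),
                 unname(wilcoxon_enum_oracle(x, y)), tolerance = 1e-12)
  }
})

test_that("tied data fall back to a corrected normal approximation near the oracle", {
  # ties at the density beta values produce (many distinct levels, occasional
  # duplicates): the corrected normal approximation tracks full enumeration
  set.seed(12)
  for (i in 1:15) {
    x <- sample(seq(0, 1, by = 0.1), 8, replace = TRUE)
    y <- sample(seq(0, 1, by = 0.1), 8, replace = TRUE)
    if (!anyDuplicated(c(x, y))) next
    got <- wilcoxon_site_test(x, y)
    want <- wilcoxon_enum_oracle(x, y)
    for (side in c("p_greater", "p_less")) {
      if (want[side] > 0.02)
        expect_lt(abs(got[side] - want[side]) / want[side], 0.10)
      expect_lt(abs(got[side] - want[side]), 0.03)
    }
  }
})

test_that("Wilcoxon p-values are symmetric and antisymmetric as expected", {
  x <- c(0.1, 0.4, 0.4, 0.8)
  p_id <- wilcoxon_site_test(x, x)  # identical multisets
  expect_gte(p_id[["p_greater"]], 0.5)
  expect_gte(p_id[["p_less"]], 0.5)
  set.seed(2)
  a <- runif(8); b <- runif(30)  # normal-approximation path
  pab <- wilcoxon_site_test(a, b)
  pba <- wilcoxon_site_test(b, a)
  expect_equal(pab[["p_greater"]], pba[["p_less"]], tolerance = 1e-12)
  expect_equal(pab[["p_less"]], pba[["p_greater"]], tolerance = 1e-12)
  expect_error(wilcoxon_site_test(NA_real_, b), "empty")
})

test_that("normal approximation matches stats::wilcox.test with ties and correction", {
  set.seed(7)
  for (i in 1:10) {
    x <- round(runif(30), 1)  # plenty of ties
    y <- round(runif(60), 1)
    got <- wilcoxon_site_test(x, y)
    ref_g <- suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                                                 exact = FALSE, correct = TRUE))
    ref_l <- suppressWarnings(stats::wilcox.test(x, y, alternative = "less",
                                                 exact = FALSE, correct = TRUE))
    expect_equal(got[["p_greater"]], ref_g$p.value, tolerance = 1e-10)
    expect_equal(got[["p_less"]], ref_l$p.value, tolerance = 1e-10)
  }
})

test_that("vectorized genome-wide counting agrees with per-site scalar tests", {
  b <- make_toy_bundle(n_samples = 70, n_sites = 120, n_mut_genes = 4, seed = 13)
  meth <- b$methylation
  meth[sample(length(meth), 150)] <- NA  # exercise missing handling
  b <- cohort_bundle("TOY", b$mutation, meth, b$expression)
  cnt <- diff_meth_counts(b, colnames(b$mutation), alpha_site = 0.05)
  for (g in colnames(b$mutation)) {
    is_mut <- b$mutation[, g] == 1L
    np <- nm <- 0L
    for (s in seq_len(nrow(meth))) {
      x <- meth[s, is_mut]; y <- meth[s, !is_mut]
      if (all(is.na(x)) || all(is.na(y))) next
      p <- wilcoxon_site_test(x, y)
      np <- np + (p[["p_greater"]] < 0.05)
      nm <- nm + (p[["p_less"]] < 0.05)
    }
    row <- cnt[cnt$gene == g, ]
    expect_identical(row$n_plus, as.integer(np))
    expect_identical(row$n_minus, as.integer(nm))
    expect_identical(row$n_m, row$n_plus + row$n_minus)
  }
})

test_that("differential counts are invariant to sample and site ordering", {
  b <- make_toy_bundle(n_samples = 60, n_sites = 80, seed = 21)
  cnt <- diff_meth_counts(b, colnames(b$mutation))
  perm_s <- sample(rownames(b$mutation))
  perm_site <- sample(rownames(b$methylation))
  b2 <- cohort_bundle("TOY", b$mutation[perm_s, , drop = FALSE],
                      b$methylation[perm_site, rev(colnames(b$methylation))],
                      b$expression)
  cnt2 <- diff_meth_counts(b2, colnames(b$mutation))
  expect_identical(cnt[, c("gene", "n_plus", "n_minus", "n_m")],
                   cnt2[, c("gene", "n_plus", "n_minus", "n_m")])
})

test_that("alpha_site = 0 yields zero counts and absent genes error", {
  b <- make_toy_bundle(seed = 3)
  cnt <- diff_methylation_count(b, "M01", alpha_site = 0)
  expect_identical(cnt$n_m, 0L)
  expect_error(diff_methylation_count(b, "NOPE"), "absent")
})

test_that("Welch t-test matches the closed-form example and stats::t.test", {
  got <- ttest_gene_expression(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(got["p"]), 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(unname(got["p"]), 0.02131164, tolerance = 1e-6)
  expect_identical(unname(got["sign"]), -1)
  ref <- stats::t.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(got["p"]), ref$p.value, tolerance = 1e-12)
  # identical groups
  expect_identical(ttest_gene_expression(c(2, 2), c(2, 2)), c(p = 1, sign = 0))
  # scale invariance
  set.seed(5)
  x <- rlnorm(10); y <- rlnorm(12)
  expect_equal(ttest_gene_expression(x, y)[["p"]],
               ttest_gene_expression(7 * x, 7 * y)[["p"]], tolerance = 1e-12)
  expect_error(ttest_gene_expression(1, c(1, 2)), ">= 2")
})

test_that("expression counts exclude the mutated gene and match scalar tests", {
  b <- make_toy_bundle(n_samples = 50, n_genes = 40, seed = 17)
  # name a mutation gene after an expression gene to test self-exclusion
  mut <- b$mutation
  colnames(mut)[1] <- rownames(b$expression)[1]
  b <- cohort_bundle("TOY", mut, b$methylation, b$expression)
  g <- colnames(mut)[1]
  cnt <- diff_expression_count(b, g, alpha_gene = 0.2)
  is_mut <- mut[, g] == 1L
  np <- nm <- 0L
  for (r in rownames(b$expression)) {
    if (r == g) next
    p <- ttest_gene_expression(b$expression[r, is_mut], b$expression[r, !is_mut])
    np <- np + (p[["p"]] < 0.2 && p[["sign"]] > 0)
    nm <- nm + (p[["p"]] < 0.2 && p[["sign"]] < 0)
  }
  expect_identical(cnt$n_plus, as.integer(np))
  expect_identical(cnt$n_minus, as.integer(nm))
  expect_identical(cnt$n_m, cnt$n_plus + cnt$n_minus)
  expect_identical(diff_expression_count(b, g, alpha_gene = 0)$n_m, 0L)
})

test_that("site and expression direction calls agree with their count summaries", {
  b <- make_toy_bundle(n_samples = 60, n_sites = 100, n_genes = 30, seed = 23)
  g <- "M01"
  calls <- site_direction_calls(b, g, alpha_site = 0.05)
  cnt <- diff_methylation_count(b, g, alpha_site = 0.05)
  expect_identical(sum(calls == "hyper"), as.integer(cnt$n_plus))
  expect_identical(sum(calls == "hypo"), as.integer(cnt$n_minus))
  ecalls <- expression_direction_calls(b, g, alpha_gene = 0.2)
  ecnt <- diff_expression_count(b, g, alpha_gene = 0.2)
  expect_identical(sum(ecalls == "up"), as.integer(ecnt$n_plus))
  expect_identical(sum(ecalls == "down"), as.integer(ecnt$n_minus))
})
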