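test_that("configuration is validated", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_sites = 0), "positive count")
  expect_error(sim_config(mutation_freq_range = c(0.4, 0.05)), "ordered pair")
  expect_error(sim_config(missing_rate = 1.5), "fraction")
  expect_error(sim_config(n_candidate_drivers = 5, n_planted_mdgs = 4,
                          n_planted_edgs = 4), "exceed")
  expect_error(sim_config(n_sites = 100, n_genes = 200), "promoter sites")
  # effects requested but too small to place at this problem size
  expect_error(sim_config(n_sites = 300, n_genes = 10,
                          driver_effect = list(fraction_of_sites_affected = 1e-5,
                                               methylation_shift = 1,
                                               fraction_of_genes_affected = 0.1,
                                               expression_log_fold = -1)),
               "too small")
  # zero fractions are a legitimate null configuration, not an error
  expect_silent(sim_config(driver_effect = list(fraction_of_sites_affected = 0,
                                                methylation_shift = 0,
                                                fraction_of_genes_affected = 0,
                                                expression_log_fold = 0)))
})

small_cfg <- function(...) {
  sim_config(n_cohorts = 2, samples_per_cohort = 60, n_sites = 600,
             n_genes = 120, n_candidate_drivers = 10, n_passengers = 8,
             n_planted_mdgs = 2, n_planted_edgs = 2, missing_rate = 0.02, ...)
}

test_that("same seed and config reproduce identical output", {
  s1 <- simulate_cohorts(small_cfg(seed = 5))
  s2 <- simulate_cohorts(small_cfg(seed = 5))
  expect_identical(s1$cohorts, s2$cohorts)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_cohorts(small_cfg(seed = 6))
  expect_false(identical(s1$cohorts[[1]]$methylation, s3$cohorts[[1]]$methylation))
})

test_that("generated matrices respect their contracts", {
  sim <- simulate_cohorts(small_cfg(seed = 9))
  for (b in sim$cohorts) {
    expect_true(all(b$mutation %in% c(0L, 1L)))
    expect_true(all(b$methylation >= 0 & b$methylation <= 1, na.rm = TRUE))
    expect_true(anyNA(b$methylation))  # missing_rate > 0
    expect_true(all(b$expression > 0))
    expect_identical(dim(b$methylation), c(600L, 60L))
  }
  tg <- sim$truth$genes
  expect_true(all(sim$truth$planted_mdgs %in% sim$truth$candidate_list))
  expect_true(all(sim$truth$planted_edgs %in% sim$truth$candidate_list))
  expect_setequal(tg$gene[tg$role == "mdg"], sim$truth$planted_mdgs)
  # planted sets disjoint when uncoupled
  expect_length(intersect(sim$truth$planted_mdgs, sim$truth$planted_edgs), 0)
})

test_that("beta values stay in [0,1] under extreme logit shifts", {
  cfg <- small_cfg(seed = 2,
                   driver_effect = list(fraction_of_sites_affected = 0.2,
                                        methylation_shift = 25,
                                        fraction_of_genes_affected = 0.1,
                                        expression_log_fold = -1))
  sim <- simulate_cohorts(cfg)
  for (b in sim$cohorts)
    expect_true(all(b$methylation >= 0 & b$methylation <= 1, na.rm = TRUE))
})

test_that("planted methylation shift moves affected sites in the stated direction", {
  cfg <- sim_config(n_cohorts = 1, samples_per_cohort = 200, n_sites = 2000,
                    n_genes = 200, n_candidate_drivers = 5, n_passengers = 0,
                    n_planted_mdgs = 1, n_planted_edgs = 0,
                    mutation_freq_range = c(0.10, 0.10),
                    driver_effect = list(fraction_of_sites_affected = 0.05,
                                         methylation_shift = 1.5,
                                         fraction_of_genes_affected = 0,
                                         expression_log_fold = 0),
                    missing_rate = 0, seed = 31)
  sim <- simulate_cohorts(cfg)
  b <- sim$cohorts[[1]]
  d <- sim$truth$planted_mdgs
  sites <- names(sim$truth$affected_sites[[d]])
  expect_length(sites, 100)  # 5% of 2000
  is_mut <- b$mutation[, d] == 1L
  dmean <- rowMeans(b$methylation[sites, is_mut, drop = FALSE]) -
    rowMeans(b$methylation[sites, !is_mut, drop = FALSE])
  expect_gte(mean(dmean > 0), 0.99)
})

test_that("coupled drivers pair promoter hyper-methylation with down-regulation", {
  cfg <- sim_config(n_cohorts = 1, samples_per_cohort = 100, n_sites = 900,
                    n_genes = 300, n_candidate_drivers = 6, n_passengers = 0,
                    n_planted_mdgs = 1, n_planted_edgs = 1,
                    couple_promoter_expression = TRUE, missing_rate = 0,
                    driver_effect = list(fraction_of_sites_affected = 0.05,
                                         methylation_shift = 2,
                                         fraction_of_genes_affected = 0.2,
                                         expression_log_fold = -1.5),
                    seed = 12)
  sim <- simulate_cohorts(cfg)
  d <- sim$truth$planted_mdgs
  expect_identical(sim$truth$planted_edgs, d)
  lf <- sim$truth$affected_targets[[d]]
  sh <- sim$truth$affected_sites[[d]]
  pm <- sim$promoter_map
  # every affected target's promoter sites are shifted opposite to its fold
  for (g in names(lf)) {
    gsites <- pm$site_id[pm$gene == g]
    expect_true(all(gsites %in% names(sh)))
    expect_true(all(sign(sh[gsites]) == -sign(lf[g])))
  }
  expect_true(any(lf > 0) && any(lf < 0))
})

test_that("a null generator yields ~alpha one-sided site rejections per tail", {
  # no planted effects: every candidate behaves as a passenger
  cfg <- sim_config(n_cohorts = 1, samples_per_cohort = 150, n_sites = 20000,
                    n_genes = 20, n_candidate_drivers = 4, n_passengers = 0,
                    n_planted_mdgs = 0, n_planted_edgs = 0, missing_rate = 0,
                    promoter_sites_per_gene = 1, seed = 77)
  sim <- simulate_cohorts(cfg)
  b <- sim$cohorts[[1]]
  cnt <- diff_meth_counts(b, sim$truth$candidate_list, alpha_site = 0.01)
  tol <- 3 * sqrt(0.01 * 0.99 / 20000)
  expect_lt(abs(mean(cnt$n_plus) / 20000 - 0.01), tol + 1e-9)
  expect_lt(abs(mean(cnt$n_minus) / 20000 - 0.01), tol + 1e-9)
})

test_that("simulation round-trips through the on-disk formats", {
  sim <- simulate_cohorts(small_cfg(seed = 3))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  b0 <- sim$cohorts[[1]]
  b1 <- load_cohort(b0$cohort_id,
                    file.path(dir, b0$cohort_id, "mutation.tsv"),
                    file.path(dir, b0$cohort_id, "methylation.tsv"),
                    file.path(dir, b0$cohort_id, "expression.tsv"))
  expect_identical(dimnames(b1$methylation), dimnames(b0$methylation))
  expect_equal(b1$methylation, b0$methylation, tolerance = 1e-12)
  expect_equal(b1$mutation, b0$mutation, ignore_attr = "mode")
  expect_equal(b1$expression, b0$expression, tolerance = 1e-12)
  pm <- read_promoter_map(file.path(dir, "promoter_map.bed"))
  expect_setequal(pm$site_id, sim$promoter_map$site_id)
  expect_identical(pm$gene[match(sim$promoter_map$site_id, pm$site_id)],
                   sim$promoter_map$gene)
})
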