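# Downstream characterization of called drivers: common dysregulated
# targets, chromatin-regulator enrichment, promoter direction calls, the
# four promoter-methylation x expression patterns, and cross-cohort
# consistency.

#' Upper-tail hypergeometric enrichment p-value
#'
#' P(X >= k) where X counts list members among `n` selected items drawn
#' without replacement from a universe of `N` items containing `K` list
#' members.
#'
#' @param N universe size.
#' @param K list (category) size within the universe.
#' @param n number of selected items.
#' @param k observed overlap.
#' @return upper-tail probability.
#' @export
#' @examples
#' hypergeom_enrichment(N = 10, K = 5, n = 4, k = 4)  # 5/210
hypergeom_enrichment <- function(N, K, n, k) {
  stopifnot(length(N) == 1L, length(K) == 1L, length(n) == 1L, length(k) == 1L)
  if (K > N || n > N) stopf("inconsistent counts: K and n must not exceed N")
  if (k > min(K, n)) stopf("inconsistent counts: k exceeds min(K, n)")
  if (k < max(0, K + n - N)) stopf("inconsistent counts: k below max(0, K + n - N)")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Combine p-values with Fisher's method
#'
#' X^2 = -2 * sum(log(p)) referred to a chi-square distribution with 2m
#' degrees of freedom. Exact zeros (possible with empirical/discrete
#' p-values) are floored at `eps` with a warning since log(0) is
#' undefined; with a single p-value the input is returned unchanged.
#'
#' @param p vector of p-values in \[0, 1\].
#' @param eps floor applied to zero p-values.
#' @return combined p-value.
#' @export
#' @examples
#' fisher_combine(c(0.05, 0.05))  # ~0.01747
fisher_combine <- function(p, eps = 1e-300) {
  if (!length(p)) stopf("fisher_combine: empty p-value list")
  stopifnot(all(p >= 0 & p <= 1))
  if (any(p == 0)) {
    warnf("fisher_combine: %d zero p-value(s) floored at %g", sum(p == 0), eps)
    p[p == 0] <- eps
  }
  x2 <- -2 * sum(log(p))
  pchisq(x2, df = 2 * length(p), lower.tail = FALSE)
}

#' Target genes dysregulated in every cohort
#'
#' Returns the genes whose expression association p-value is below `alpha`
#' in all listed cohorts — the common dysregulated target set N_1 of a
#' driver across the cohorts where it shows a genome-wide methylation
#' association. Direction consistency across cohorts is not required.
#'
#' @param per_cohort_p named list: cohort ID -> named numeric vector of
#'   per-gene p-values.
#' @param cohorts cohort IDs to intersect over (default: all in the list).
#' @param alpha per-gene significance threshold.
#' @return character vector of common target genes.
#' @export
identify_common_targets <- function(per_cohort_p, cohorts = names(per_cohort_p),
                                    alpha = 0.05) {
  if (!length(cohorts)) stopf("no cohorts supplied: driver not eligible for this analysis")
  missing <- setdiff(cohorts, names(per_cohort_p))
  if (length(missing)) stopf("no p-values for cohort(s): %s", paste(missing, collapse = ", "))
  sets <- lapply(cohorts, function(cid) {
    p <- per_cohort_p[[cid]]
    names(p)[!is.na(p) & p < alpha]
  })
  Reduce(intersect, sets)
}

#' Enrichment of a regulator list among target genes
#'
#' Tests whether a chromatin-regulator list is over-represented among a
#' driver's dysregulated target genes, by an upper-tail hypergeometric
#' test. Both the target set and the regulator list are restricted to the
#' measured universe before testing.
#'
#' @param targets dysregulated target genes.
#' @param regulators regulator gene list.
#' @param universe measured gene universe (e.g. all expression genes).
#' @return one-row data frame: n_universe, n_targets, n_list, overlap, p.
#' @export
regulator_enrichment <- function(targets, regulators, universe) {
  targets <- intersect(targets, universe)
  regulators <- intersect(regulators, universe)
  k <- length(intersect(targets, regulators))
  p <- hypergeom_enrichment(length(universe), length(regulators),
                            length(targets), k)
  data.frame(n_universe = length(universe), n_targets = length(targets),
             n_list = length(regulators), overlap = k, p = p)
}

#' Promoter-level direction call from site-level calls
#'
#' Majority vote over the hyper/hypo calls of a gene's promoter CpG sites:
#' `hyper` when strictly more sites are hyper- than hypo-methylated,
#' `hypo` when strictly fewer, and `none` on ties or when no promoter site
#' is differentially methylated (or no site is mapped).
#'
#' @param site_calls character vector of `"hyper"`/`"hypo"`/`"none"` calls
#'   for the gene's promoter sites (may be empty).
#' @return `"hyper"`, `"hypo"` or `"none"`.
#' @export
promoter_direction <- function(site_calls) {
  n_hyper <- sum(site_calls == "hyper")
  n_hypo <- sum(site_calls == "hypo")
  if (n_hyper == 0 && n_hypo == 0) return("none")
  if (n_hyper == n_hypo) return("none")
  if (n_hyper > n_hypo) "hyper" else "hypo"
}

#' Promoter methylation direction calls for all mapped genes
#'
#' Computes site-level direction calls for the driver
#' ([site_direction_calls()]) and reduces them to one call per gene by
#' majority vote over its promoter sites ([promoter_direction()]). Sites
#' absent from the (QC-filtered) methylation matrix are ignored; genes
#' with no surviving site are `none`.
#'
#' @param bundle a [cohort_bundle()].
#' @param driver mutated gene whose status defines the groups.
#' @param promoter_map data frame (gene, site_id) as from
#'   [read_promoter_map()].
#' @param alpha_site site-level significance.
#' @param cache optional [site_rank_cache()].
#' @return named character vector over mapped genes.
#' @export
promoter_direction_calls <- function(bundle, driver, promoter_map,
                                     alpha_site = 0.01, cache = NULL) {
  site_calls <- site_direction_calls(bundle, driver, alpha_site = alpha_site,
                                     cache = cache)
  pm <- promoter_map[promoter_map$site_id %in% names(site_calls), , drop = FALSE]
  genes <- unique(promoter_map$gene)
  calls <- setNames(rep("none", length(genes)), genes)
  if (nrow(pm)) {
    by_gene <- split(site_calls[pm$site_id], pm$gene)
    calls[names(by_gene)] <- vapply(by_gene, promoter_direction, character(1))
  }
  calls
}

#' Promoter-methylation x expression pattern tests
#'
#' For each cohort, crosses per-gene promoter methylation calls
#' (`hyper`/`hypo`/`none`) with expression calls (`up`/`down`/`none`) over
#' a shared measured universe and tests each of the four joint patterns
#' (`++`, `+-`, `-+`, `--`; methylation direction first) for excess over
#' chance with an upper-tail hypergeometric test (K = genes with the
#' methylation direction, n = genes with the expression direction, k =
#' genes with both, N = universe). The overall overlap of differentially
#' methylated (DM) and differentially expressed (DE) genes is tested the
#' same way. Per-cohort p-values are combined across cohorts with
#' [fisher_combine()].
#'
#' @param driver driver gene label (carried through to the output).
#' @param dm_calls named list: cohort -> named vector of
#'   `"hyper"`/`"hypo"`/`"none"` promoter calls.
#' @param de_calls named list: cohort -> named vector of
#'   `"up"`/`"down"`/`"none"` expression calls.
#' @return object of class `pattern_result`: list with `summary` (one-row
#'   data frame: driver, n_cohorts, dm_count, de_count, dm_and_de_frac,
#'   p_dmde, p_mm, p_pm, p_mp, p_pp) and `per_cohort` (per-cohort counts
#'   and p-values).
#' @export
pattern_tests <- function(driver, dm_calls, de_calls) {
  cohorts <- intersect(names(dm_calls), names(de_calls))
  if (!length(cohorts)) stopf("pattern_tests: no shared cohorts")
  pats <- list(pp = c("hyper", "up"), pm = c("hyper", "down"),
               mp = c("hypo", "up"), mm = c("hypo", "down"))
  rows <- list()
  for (cid in cohorts) {
    dm <- dm_calls[[cid]]
    de <- de_calls[[cid]]
    universe <- intersect(names(dm), names(de))
    if (!length(universe)) stopf("pattern_tests: empty measured universe in cohort '%s'", cid)
    dm <- dm[universe]; de <- de[universe]
    N <- length(universe)
    dm_set <- universe[dm != "none"]
    de_set <- universe[de != "none"]
    k_dmde <- length(intersect(dm_set, de_set))
    row <- data.frame(cohort = cid, n_universe = N,
                      dm_count = length(dm_set), de_count = length(de_set),
                      dm_and_de = k_dmde,
                      p_dmde = hypergeom_enrichment(N, length(dm_set),
                                                    length(de_set), k_dmde),
                      stringsAsFactors = FALSE)
    for (pn in names(pats)) {
      K <- sum(dm == pats[[pn]][1])
      n <- sum(de == pats[[pn]][2])
      k <- sum(dm == pats[[pn]][1] & de == pats[[pn]][2])
      row[[paste0("n_", pn)]] <- k
      row[[paste0("p_", pn)]] <- hypergeom_enrichment(N, K, n, k)
    }
    rows[[cid]] <- row
  }
  per_cohort <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  comb <- function(col) fisher_combine(per_cohort[[col]])
  summary <- data.frame(
    driver = driver, n_cohorts = nrow(per_cohort),
    dm_count = mean(per_cohort$dm_count), de_count = mean(per_cohort$de_count),
    dm_and_de_frac = mean(ifelse(per_cohort$de_count > 0,
                                 per_cohort$dm_and_de / per_cohort$de_count, NA)),
    p_dmde = comb("p_dmde"), p_mm = comb("p_mm"), p_pm = comb("p_pm"),
    p_mp = comb("p_mp"), p_pp = comb("p_pp"),
    stringsAsFactors = FALSE)
  structure(list(summary = summary, per_cohort = per_cohort),
            class = "pattern_result")
}

#' @export
print.pattern_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("pattern_result '%s' over %d cohort(s):\n", s$driver, s$n_cohorts))
  cat(sprintf("  mean |DM| = %.1f, |DE| = %.1f, |DM&DE|/|DE| = %.2f\n",
              s$dm_count, s$de_count, s$dm_and_de_frac))
  cat(sprintf("  p(DM.DE)=%.3g  p(--)=%.3g  p(+-)=%.3g  p(-+)=%.3g  p(++)=%.3g\n",
              s$p_dmde, s$p_mm, s$p_pm, s$p_mp, s$p_pp))
  invisible(x)
}

#' Cross-cohort consistency of per-cohort gene sets
#'
#' For every pair of cohorts, tests whether the overlap of the two
#' per-cohort gene sets exceeds chance (upper-tail hypergeometric over the
#' shared measured universe) and returns the median p-value over pairs.
#' A single cohort yields `NA` (no pair to compare).
#'
#' @param sets named list: cohort -> character vector of genes.
#' @param universes named list: cohort -> measured gene universe.
#' @return list with `median_p` and `pairs` (data frame cohort1, cohort2,
#'   n_universe, size1, size2, overlap, p).
#' @export
cross_cohort_consistency <- function(sets, universes) {
  ids <- intersect(names(sets), names(universes))
  if (length(ids) < 2L)
    return(list(median_p = NA_real_,
                pairs = data.frame(cohort1 = character(), cohort2 = character(),
                                   n_universe = integer(), size1 = integer(),
                                   size2 = integer(), overlap = integer(),
                                   p = numeric())))
  prs <- utils::combn(ids, 2L)
  rows <- lapply(seq_len(ncol(prs)), function(j) {
    c1 <- prs[1, j]; c2 <- prs[2, j]
    shared <- intersect(universes[[c1]], universes[[c2]])
    s1 <- intersect(sets[[c1]], shared)
    s2 <- intersect(sets[[c2]], shared)
    k <- length(intersect(s1, s2))
    data.frame(cohort1 = c1, cohort2 = c2, n_universe = length(shared),
               size1 = length(s1), size2 = length(s2), overlap = k,
               p = hypergeom_enrichment(length(shared), length(s1),
                                        length(s2), k),
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(median_p = median(pairs$p), pairs = pairs)
}

#' Full pattern analysis for one driver
#'
#' Computes, for every cohort in `cohorts_used` (typically the
#' intersection of the driver's methylation- and expression-significant
#' cohorts), per-gene promoter methylation calls and expression calls,
#' runs [pattern_tests()], and adds the pairwise cross-cohort consistency
#' median p-values for the differentially methylated and differentially
#' expressed gene sets.
#'
#' @param cohorts named list of [cohort_bundle()] objects.
#' @param driver driver gene.
#' @param promoter_map data frame (gene, site_id).
#' @param cohorts_used cohort IDs to analyze (default: all).
#' @param alpha_site site-level significance for methylation calls.
#' @param alpha_expr gene-level significance for expression calls.
#' @param caches optional named list of [site_rank_cache()] per cohort.
#' @return a `pattern_result` whose `summary` also carries
#'   `p_methyl_median` and `p_exp_median`, with the per-pair detail in
#'   `consistency`.
#' @export
analyze_driver_patterns <- function(cohorts, driver, promoter_map,
                                    cohorts_used = names(cohorts),
                                    alpha_site = 0.01, alpha_expr = 0.05,
                                    caches = NULL) {
  if (!length(cohorts_used)) stopf("driver '%s': no cohorts to analyze", driver)
  dm_calls <- list(); de_calls <- list()
  dm_sets <- list(); de_sets <- list(); universes <- list()
  for (cid in cohorts_used) {
    b <- cohorts[[cid]]
    if (is.null(b)) stopf("unknown cohort '%s'", cid)
    dm <- promoter_direction_calls(b, driver, promoter_map,
                                   alpha_site = alpha_site,
                                   cache = caches[[cid]])
    de <- expression_direction_calls(b, driver, alpha_gene = alpha_expr)
    universe <- intersect(names(dm), names(de))
    dm_calls[[cid]] <- dm[universe]
    de_calls[[cid]] <- de[universe]
    dm_sets[[cid]] <- universe[dm[universe] != "none"]
    de_sets[[cid]] <- universe[de[universe] != "none"]
    universes[[cid]] <- universe
  }
  res <- pattern_tests(driver, dm_calls, de_calls)
  cons_m <- cross_cohort_consistency(dm_sets, universes)
  cons_e <- cross_cohort_consistency(de_sets, universes)
  res$summary$p_methyl_median <- cons_m$median_p
  res$summary$p_exp_median <- cons_e$median_p
  res$consistency <- list(methylation = cons_m, expression = cons_e)
  res$dm_sets <- dm_sets
  res$de_sets <- de_sets
  res
}
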