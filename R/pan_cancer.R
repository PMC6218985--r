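# Pan-cancer aggregation: resampling p-values over the null pool, grouped
# Benjamini-Hochberg adjustment, and assembly of driver calls.

#' Cohorts in which a gene is testable
#'
#' Returns the set A_i of cohorts in which `gene` is mutated in at least
#' `min_mutated` samples that also have data for the given modality. Genes
#' with an empty A_i are not tested.
#'
#' @param cohorts list of [cohort_bundle()] objects.
#' @param gene gene identifier.
#' @param min_mutated minimal mutated-sample count.
#' @param modality `"methylation"` or `"expression"`.
#' @return character vector of cohort IDs.
#' @export
eligible_cohorts <- function(cohorts, gene, min_mutated = 5L,
                             modality = c("methylation", "expression")) {
  modality <- match.arg(modality)
  ids <- character()
  for (b in cohorts) {
    samples <- modality_samples(b, modality)
    if (!length(samples) || !(gene %in% colnames(b$mutation))) next
    if (sum(b$mutation[samples, gene]) >= min_mutated)
      ids <- c(ids, b$cohort_id)
  }
  ids
}

#' Resample null sums from the pool
#'
#' Draws `B` sums of `m` pool counts sampled uniformly with replacement.
#' Resampling is chunked so memory stays bounded for large `B`.
#'
#' @param pool a [build_null_pool()] object or numeric count vector.
#' @param m number of pool draws per sum (the gene's |A_i|).
#' @param B number of resampled sums.
#' @param chunk resamples per chunk.
#' @return numeric vector of `B` sums.
#' @export
resample_null_sums <- function(pool, m, B = 1e6, chunk = 1e5) {
  v <- .pool_values(pool)
  if (!length(v)) stopf("null pool is empty")
  stopifnot(m >= 1L, B >= 1)
  B <- as.integer(B)
  out <- numeric(B)
  done <- 0L
  while (done < B) {
    nb <- min(as.integer(chunk), B - done)
    draws <- matrix(v[sample.int(length(v), nb * m, replace = TRUE)], nrow = m)
    out[done + seq_len(nb)] <- colSums(draws)
    done <- done + nb
  }
  out
}

#' Pan-cancer resampling p-value
#'
#' Compares the observed total count (summed over the gene's eligible
#' cohorts) with `B` resampled sums of `|A_i|` draws from the null pool:
#' p = (1/B) * sum(I(observed_sum <= resampled sum)). An exact zero means
#' "below 1/B" and is annotated when written. Resampled sums may be
#' supplied (and shared across genes with the same `|A_i|`), which is
#' statistically equivalent under the null and saves work.
#'
#' @param observed_sum observed total differential count.
#' @param pool null pool (ignored when `resampled` is given).
#' @param m number of cohorts summed over (|A_i|).
#' @param B number of resamples.
#' @param seed optional integer seed.
#' @param resampled optional pre-drawn sums from [resample_null_sums()].
#' @return resampling p-value in \[0,1\].
#' @export
pan_cancer_p <- function(observed_sum, pool = NULL, m = 1L, B = 1e6,
                         seed = NULL, resampled = NULL) {
  stopifnot(is.numeric(observed_sum), length(observed_sum) == 1L)
  if (is.null(resampled)) {
    if (!is.null(seed)) set.seed(seed)
    resampled <- resample_null_sums(pool, m = m, B = B)
  }
  mean(observed_sum <= resampled)
}

#' Exact pan-cancer p-value by convolution
#'
#' Exact P(sum of `m` i.i.d. pool draws >= observed_sum), computed by
#' m-fold convolution of the pool's empirical count distribution. Serves
#' as the enumeration oracle for [pan_cancer_p()]; with `m = 1` it reduces
#' to [empirical_p_per_cancer()].
#'
#' @param observed_sum observed total count (non-negative).
#' @param pool null pool or numeric count vector (non-negative integers).
#' @param m number of draws summed.
#' @param max_support guard on the convolution support size.
#' @return exact tail probability.
#' @export
#' @examples
#' pan_cancer_p_exact(6, c(1, 2, 3), m = 2)  # 1/9
pan_cancer_p_exact <- function(observed_sum, pool, m, max_support = 5e6) {
  v <- .pool_values(pool)
  if (!length(v)) stopf("null pool is empty")
  if (any(v < 0) || any(v != round(v))) stopf("pool counts must be non-negative integers")
  stopifnot(m >= 1L, observed_sum >= 0)
  if (max(v) * m + 1 > max_support)
    stopf("convolution support too large (%g); use Monte-Carlo pan_cancer_p()",
          max(v) * m + 1)
  p0 <- tabulate(v + 1L, nbins = max(v) + 1L) / length(v)  # support 0..max(v)
  pm <- p0
  if (m > 1L) for (i in 2:m) {
    res <- numeric(length(pm) + length(p0) - 1L)
    for (j in seq_along(p0)) {
      if (p0[j] == 0) next
      idx <- j:(j + length(pm) - 1L)
      res[idx] <- res[idx] + p0[j] * pm
    }
    pm <- res
  }
  support <- seq_along(pm) - 1L
  min(1, max(0, sum(pm[support >= observed_sum])))
}

#' Grouped Benjamini-Hochberg adjustment
#'
#' Standard BH step-up applied independently within groups of genes tested
#' in the same number of cohorts (|A_i| strata). p-values are comparable
#' within a stratum — a gene summing counts over more cohorts has a
#' different null — so the adjustment is stratified rather than pooled.
#'
#' @param p named numeric vector of pan-cancer p-values.
#' @param groups vector (same length/names) of stratum labels, typically
#'   |A_i|.
#' @return named vector of adjusted p-values (capped at 1, monotone within
#'   each stratum).
#' @export
#' @examples
#' bh_adjust_grouped(c(a = 0.01, b = 0.02, c = 0.03, d = 0.04),
#'                   groups = c(1, 1, 1, 1))
bh_adjust_grouped <- function(p, groups) {
  stopifnot(length(p) == length(groups), all(p >= 0 & p <= 1, na.rm = TRUE))
  adj <- p
  for (g in unique(groups)) {
    idx <- which(groups == g)
    adj[idx] <- p.adjust(p[idx], method = "BH")
  }
  adj
}

#' Assemble driver calls
#'
#' Combines per-cohort calls with pan-cancer and adjusted p-values into one
#' row per gene. `T_i` (cohorts with a significant per-cohort association)
#' is partitioned into `T_plus`/`T_minus` by direction; the overall
#' direction `D` is `both` when both sides are non-empty, the single side's
#' label otherwise, and `NA` when `T_i` is empty (a gene can be pan-cancer
#' significant through consistent sub-threshold shifts without any single
#' cohort reaching significance). A gene is called a driver when its
#' adjusted p-value is below `alpha`.
#'
#' @param per_cancer data frame with columns gene, cohort, n_plus, n_minus,
#'   n_m, p, direction (one row per gene x eligible cohort).
#' @param pan_p named vector of pan-cancer p-values.
#' @param p_adj named vector of adjusted p-values.
#' @param alpha driver-call threshold on the adjusted p-value.
#' @param modality `"methylation"` or `"expression"`.
#' @param B resampling depth (for the p-value floor annotation).
#' @return data frame, one row per gene: gene, n_cohorts_eligible,
#'   n_signif, p, p_label, p_adj, direction, t_plus, t_minus, is_driver.
#' @export
call_drivers <- function(per_cancer, pan_p, p_adj, alpha = 0.05,
                         modality = c("methylation", "expression"), B = 1e6) {
  modality <- match.arg(modality)
  genes <- names(pan_p)
  if (is.null(genes)) stopf("pan_p must be a named vector")
  lab <- if (modality == "methylation") c("hyper", "hypo") else c("up", "down")
  rows <- lapply(genes, function(g) {
    pc <- per_cancer[per_cancer$gene == g, , drop = FALSE]
    if (!nrow(pc)) stopf("gene '%s' has a pan-cancer p-value but no per-cohort calls", g)
    t_plus <- pc$cohort[pc$direction == lab[1]]
    t_minus <- pc$cohort[pc$direction == lab[2]]
    direction <- if (!length(t_plus) && !length(t_minus)) NA_character_
      else if (length(t_plus) && length(t_minus)) "both"
      else if (length(t_plus)) lab[1] else lab[2]
    data.frame(gene = g,
               n_cohorts_eligible = nrow(pc),
               cohorts_eligible = paste(sort(pc$cohort), collapse = ","),
               n_signif = length(t_plus) + length(t_minus),
               p = unname(pan_p[g]),
               p_label = p_floor_label(unname(pan_p[g]), 1 / B),
               p_adj = unname(p_adj[g]),
               direction = direction,
               t_plus = paste(sort(t_plus), collapse = ","),
               t_minus = paste(sort(t_minus), collapse = ","),
               is_driver = unname(p_adj[g]) < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(-out$n_cohorts_eligible, out$p, out$gene), , drop = FALSE]
}

#' Pan-cancer driver-gene analysis
#'
#' End-to-end caller for one modality: determines each candidate's
#' eligible cohorts (mutated in at least `min_mutated` samples with
#' modality data), computes genome-wide differential counts per (gene,
#' cohort), builds the passenger-gene null pool, converts counts into
#' per-cohort empirical p-values with direction calls, aggregates counts
#' into pan-cancer resampling p-values (resampled sums are drawn once per
#' |A_i| stratum and shared across its genes), applies the grouped BH
#' adjustment and assembles driver calls.
#'
#' @param cohorts list (or single) of [cohort_bundle()] objects.
#' @param cdg_list candidate driver gene list.
#' @param modality `"methylation"` or `"expression"`.
#' @param alpha_site site-level (methylation, default 0.01) or gene-level
#'   (expression, default 0.05) significance for the counting step.
#' @param alpha_cohort per-cohort significance for direction calls.
#' @param alpha driver-call threshold on the adjusted pan-cancer p.
#' @param min_mutated eligibility threshold on mutated samples.
#' @param top_k per-cohort cap on null-pool genes.
#' @param B number of pan-cancer resamples.
#' @param seed optional integer seed for the resampling.
#' @param pool optional pre-built [build_null_pool()] (reused as-is).
#' @param caches optional named list of [site_rank_cache()] per cohort.
#' @return object of class `driver_result`: list with `calls` (one row per
#'   tested gene), `per_cancer` (per gene x cohort counts, empirical p and
#'   direction), `pool`, `modality` and `params`.
#' @export
call_driver_genes <- function(cohorts, cdg_list,
                              modality = c("methylation", "expression"),
                              alpha_site = NULL, alpha_cohort = 0.05,
                              alpha = 0.05, min_mutated = 5L, top_k = 500L,
                              B = 1e6, seed = NULL, pool = NULL, caches = NULL) {
  modality <- match.arg(modality)
  if (inherits(cohorts, "cohort_bundle")) cohorts <- list(cohorts)
  if (is.null(alpha_site)) alpha_site <- if (modality == "methylation") 0.01 else 0.05
  if (!is.null(seed)) set.seed(seed)

  if (modality == "methylation" && is.null(caches)) {
    caches <- lapply(cohorts, function(b)
      site_rank_cache(b$methylation[, modality_samples(b, "methylation"), drop = FALSE]))
    names(caches) <- vapply(cohorts, function(b) b$cohort_id, character(1))
  }

  # A_i per candidate; drop untestable genes
  a_sets <- lapply(setNames(cdg_list, cdg_list), function(g)
    eligible_cohorts(cohorts, g, min_mutated = min_mutated, modality = modality))
  dropped <- names(a_sets)[lengths(a_sets) == 0L]
  if (length(dropped))
    message(sprintf("%d candidate gene(s) not mutated in >= %d samples in any cohort: %s",
                    length(dropped), min_mutated,
                    paste(head(dropped, 5), collapse = ", ")))
  a_sets <- a_sets[lengths(a_sets) > 0L]
  if (!length(a_sets)) stopf("no testable candidate gene")

  # observed counts per (gene, cohort in A_i)
  pc_rows <- list()
  for (b in cohorts) {
    genes_here <- names(a_sets)[vapply(a_sets, function(a) b$cohort_id %in% a, logical(1))]
    if (!length(genes_here)) next
    pc_rows[[b$cohort_id]] <- if (modality == "methylation") {
      diff_meth_counts(b, genes_here, alpha_site = alpha_site,
                       cache = caches[[b$cohort_id]])
    } else {
      diff_expr_counts(b, genes_here, alpha_gene = alpha_site)
    }
  }
  per_cancer <- do.call(rbind, c(pc_rows, list(make.row.names = FALSE)))

  if (is.null(pool)) {
    null_genes <- select_null_genes(cohorts, cdg_list, min_mutated = min_mutated,
                                    top_k = top_k, modality = modality)
    pool <- build_null_pool(cohorts, null_genes, modality = modality,
                            alpha_site = alpha_site, caches = caches)
  }

  per_cancer$p <- vapply(per_cancer$n_m, empirical_p_per_cancer, numeric(1), pool = pool)
  per_cancer$p_label <- p_floor_label(per_cancer$p, 1 / pool$size)
  per_cancer$direction <- mapply(classify_direction, per_cancer$p,
                                 per_cancer$n_plus, per_cancer$n_minus,
                                 MoreArgs = list(alpha_cohort = alpha_cohort,
                                                 modality = modality))

  # pan-cancer resampling p, resampled sums shared within |A_i| strata
  obs_sum <- tapply(per_cancer$n_m, per_cancer$gene, sum)
  m_of <- lengths(a_sets)[names(obs_sum)]
  pan_p <- setNames(numeric(length(obs_sum)), names(obs_sum))
  for (m in sort(unique(m_of))) {
    sums <- resample_null_sums(pool, m = m, B = B)
    for (g in names(obs_sum)[m_of == m])
      pan_p[g] <- mean(obs_sum[[g]] <= sums)
  }
  p_adj <- bh_adjust_grouped(pan_p, groups = m_of)

  calls <- call_drivers(per_cancer, pan_p, p_adj, alpha = alpha,
                        modality = modality, B = B)
  structure(list(calls = calls, per_cancer = per_cancer, pool = pool,
                 modality = modality,
                 params = list(alpha_site = alpha_site,
                               alpha_cohort = alpha_cohort, alpha = alpha,
                               min_mutated = min_mutated, top_k = top_k,
                               B = B, seed = seed)),
            class = "driver_result")
}

#' @export
print.driver_result <- function(x, ...) {
  nd <- sum(x$calls$is_driver)
  cat(sprintf("driver_result (%s): %d genes tested, %d called (adjusted p < %g)\n",
              x$modality, nrow(x$calls), nd, x$params$alpha))
  if (nd) print(utils::head(x$calls[x$calls$is_driver,
                                    c("gene", "n_cohorts_eligible", "n_signif",
                                      "p_label", "p_adj", "direction")], 10))
  invisible(x)
}
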