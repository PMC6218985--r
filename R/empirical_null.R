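# Passenger-gene empirical null.
#
# The null distribution of the genome-wide differential count is built
# from passenger mutations: genes mutated in at least `min_mutated`
# samples that are not on the candidate driver list, capped at the top_k
# most frequently mutated genes per cohort. Every (passenger gene, cohort)
# pair contributes one count to the pool; observed candidate counts are
# then ranked against this pool. Passenger mutations carry whatever
# residual genome-wide association background mutational processes
# produce, which a random relabeling of samples cannot, so the pool is
# the primary null; a random-split null is provided as a sensitivity
# check.

#' Select passenger genes for the null pool
#'
#' Per cohort, keeps genes mutated in at least `min_mutated` samples with
#' data for the given modality, removes candidate driver genes, and
#' truncates to the `top_k` most frequently mutated genes (ties at the
#' cutoff broken by lexicographic gene ID, making the selection
#' deterministic and invariant to input ordering).
#'
#' @param cohorts list of [cohort_bundle()] objects.
#' @param cdg_list candidate driver genes to exclude.
#' @param min_mutated minimal number of mutated samples.
#' @param top_k per-cohort cap on selected genes.
#' @param modality `"methylation"` or `"expression"` (determines which
#'   samples count as having data).
#' @return named list: cohort ID -> character vector of null genes.
#' @export
select_null_genes <- function(cohorts, cdg_list, min_mutated = 5L, top_k = 500L,
                              modality = c("methylation", "expression")) {
  modality <- match.arg(modality)
  stopifnot(min_mutated >= 1L, top_k >= 1L)
  out <- list()
  for (b in cohorts) {
    samples <- modality_samples(b, modality)
    if (!length(samples)) { out[[b$cohort_id]] <- character(); next }
    cnt <- colSums(b$mutation[samples, , drop = FALSE])
    cnt <- cnt[!(names(cnt) %in% cdg_list) & cnt >= min_mutated]
    sel <- names(cnt)[order(-cnt, names(cnt))]
    out[[b$cohort_id]] <- head(sel, top_k)
  }
  if (!any(lengths(out) > 0L))
    stopf("no passenger gene mutated in >= %d samples in any cohort", min_mutated)
  out
}

#' Build the empirical null pool of differential counts
#'
#' Runs the genome-wide counting operation ([diff_meth_counts()] or
#' [diff_expr_counts()]) for every (null gene, cohort) pair and collects
#' the resulting counts. All pairs are retained (a gene passing the
#' selection in several cohorts contributes one value per cohort).
#'
#' @param cohorts list of [cohort_bundle()] objects.
#' @param null_genes per-cohort gene sets from [select_null_genes()].
#' @param modality `"methylation"` or `"expression"`.
#' @param alpha_site site-level (methylation) or gene-level (expression)
#'   significance level for the counting operation.
#' @param caches optional named list of [site_rank_cache()] objects keyed
#'   by cohort ID (methylation only).
#' @return object of class `null_pool`: list with `values` (data frame
#'   gene, cohort, n_m with provenance), `modality` and `size`.
#' @export
build_null_pool <- function(cohorts, null_genes,
                            modality = c("methylation", "expression"),
                            alpha_site = if (modality[1] == "methylation") 0.01 else 0.05,
                            caches = NULL) {
  modality <- match.arg(modality)
  rows <- list()
  for (b in cohorts) {
    genes <- null_genes[[b$cohort_id]]
    if (!length(genes)) next
    cnt <- if (modality == "methylation") {
      diff_meth_counts(b, genes, alpha_site = alpha_site,
                       cache = caches[[b$cohort_id]])
    } else {
      diff_expr_counts(b, genes, alpha_gene = alpha_site)
    }
    rows[[b$cohort_id]] <- cnt[, c("gene", "cohort", "n_m")]
  }
  if (!length(rows)) stopf("null pool is empty: no null genes in any cohort")
  values <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(list(values = values, modality = modality, size = nrow(values)),
            class = "null_pool")
}

#' @export
print.null_pool <- function(x, ...) {
  cat(sprintf("null_pool (%s): %d (gene, cohort) counts; median n_m = %g\n",
              x$modality, x$size, median(x$values$n_m)))
  invisible(x)
}

# Accept a null_pool or a bare numeric vector of counts.
.pool_values <- function(pool) {
  if (inherits(pool, "null_pool")) return(pool$values$n_m)
  if (is.numeric(pool)) return(pool)
  stopf("expected a null_pool or a numeric vector of counts")
}

#' Per-cohort empirical p-value against the null pool
#'
#' The p-value is the proportion of pool counts greater than or equal to
#' the observed count: p = (1/|pool|) * sum(I(observed <= pool value)).
#' A result of exactly zero means "below 1/|pool|" and is annotated as
#' such where results are written ([p_floor_label()]); no small-sample
#' correction is applied.
#'
#' @param observed_nm observed genome-wide differential count (or a
#'   one-row count data frame with an `n_m` column).
#' @param pool a [build_null_pool()] object or numeric vector of counts.
#' @return empirical p-value in \[0,1\].
#' @export
#' @examples
#' empirical_p_per_cancer(12, c(5, 10, 15))  # 1/3
empirical_p_per_cancer <- function(observed_nm, pool) {
  if (is.data.frame(observed_nm)) observed_nm <- observed_nm$n_m
  stopifnot(is.numeric(observed_nm), length(observed_nm) == 1L)
  v <- .pool_values(pool)
  if (!length(v)) stopf("null pool is empty")
  mean(observed_nm <= v)
}

#' Classify the genome-wide direction of a per-cohort association
#'
#' A gene's effect in a cohort is `hyper` (methylation) / `up` (expression)
#' when the empirical p-value is below `alpha_cohort` and strictly more
#' sites/genes moved up than down, `hypo`/`down` when significant and the
#' up-count is less than or equal to the down-count (ties go to the
#' hypo/down branch), and `none` otherwise.
#'
#' @param p_ik per-cohort empirical p-value.
#' @param n_plus,n_minus directional counts.
#' @param alpha_cohort per-cohort significance level.
#' @param modality `"methylation"` or `"expression"` (label set only).
#' @return `"hyper"`/`"hypo"`/`"none"` or `"up"`/`"down"`/`"none"`.
#' @export
classify_direction <- function(p_ik, n_plus, n_minus, alpha_cohort = 0.05,
                               modality = c("methylation", "expression")) {
  modality <- match.arg(modality)
  stopifnot(n_plus >= 0, n_minus >= 0)
  lab <- if (modality == "methylation") c("hyper", "hypo") else c("up", "down")
  if (is.na(p_ik) || p_ik >= alpha_cohort) return("none")
  if (n_plus > n_minus) lab[1] else lab[2]
}

#' Random-split sensitivity null
#'
#' Generates a null distribution of genome-wide differential counts by
#' randomly splitting a cohort's samples into pseudo-mutated and
#' pseudo-wild-type groups, sweeping the pseudo-mutation percentage over
#' `pct` (default 5..40% in steps of 1) with `reps` random splits each:
#' 36 x 10 = 360 counts per cohort at the defaults. The pseudo-mutated
#' group size is `round(pct/100 * n)` with a minimum of one sample. This
#' null ignores any association between real passenger mutations and
#' methylation, so on real tumor data it tends to sit below the
#' passenger-gene pool; it is provided as a sensitivity check.
#'
#' @param bundle a [cohort_bundle()].
#' @param pct integer percentages to sweep.
#' @param reps random splits per percentage.
#' @param alpha_site site-level significance for the counting.
#' @param seed optional integer seed.
#' @param cache optional [site_rank_cache()].
#' @return integer vector of `length(pct) * reps` counts, with attributes
#'   `pct` and `rep` recording the split parameters.
#' @export
random_split_null <- function(bundle, pct = 5:40, reps = 10L, alpha_site = 0.01,
                              seed = NULL, cache = NULL) {
  stopifnot(inherits(bundle, "cohort_bundle"), all(pct > 0), all(pct <= 100))
  samples <- modality_samples(bundle, "methylation")
  n <- length(samples)
  if (n < 2L) stopf("cohort '%s': too few samples for random splits", bundle$cohort_id)
  if (!is.null(seed)) set.seed(seed)
  sizes <- pmax(1L, as.integer(round(pct / 100 * n)))
  if (max(sizes) >= n)
    stopf("cohort '%s': largest split leaves no wild-type samples", bundle$cohort_id)
  grid <- expand.grid(rep = seq_len(reps), pct = pct)[, c("pct", "rep")]
  groups <- matrix(0, n, nrow(grid))
  for (j in seq_len(nrow(grid))) {
    sz <- sizes[match(grid$pct[j], pct)]
    groups[sample.int(n, sz), j] <- 1
  }
  meth <- bundle$methylation[, samples, drop = FALSE]
  if (!is.null(cache) && !identical(cache$samples, samples)) cache <- NULL
  if (is.null(cache)) cache <- site_rank_cache(meth)
  cnt <- .counts_from_groups(cache, groups, alpha_site)
  structure(cnt$n_m, pct = grid$pct, rep = grid$rep)
}
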