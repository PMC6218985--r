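# Synthetic multi-omics cohort generator.
#
# The generator emulates the statistical structure the driver-calling
# pipeline assumes: bimodal beta values enriched near 0 and 1, extremely
# unbalanced mutated/wild-type group sizes (per-gene mutation frequencies
# drawn from 5-40%), planted driver genes that shift methylation on the
# logit scale at a subset of sites and/or scale expression of a subset of
# target genes, and passenger genes with no systematic effect.

#' Configuration for synthetic multi-omics cohorts
#'
#' Builds and validates the parameter set consumed by [simulate_cohorts()].
#' Defaults describe a desk-scale pan-cancer study: 3 tumor cohorts of 200
#' samples, 20,000 CpG sites, 2,000 expression genes, a 50-gene candidate
#' driver list (of which a few carry planted effects) and 150 passenger
#' genes per cohort that feed the empirical null pool. The passenger count
#' is deliberately several times the candidate count: the pan-cancer
#' p-values are resolved against the empirical pool, so the pool must be
#' large enough to estimate the tail quantiles at which the grouped BH
#' adjustment operates (at full pan-cancer scale, 20 tumor types, this
#' design yields pools of several thousand entries).
#'
#' @param n_cohorts number of tumor cohorts.
#' @param samples_per_cohort samples per cohort.
#' @param n_sites number of CpG sites.
#' @param n_genes number of expression (target) genes. The first
#'   `n_genes * promoter_sites_per_gene` CpG sites are assigned to gene
#'   promoters (1,500 bp upstream of the TSS by convention); the remainder
#'   are intergenic.
#' @param n_candidate_drivers size of the candidate driver (CDG) list.
#' @param n_passengers number of mutated passenger genes outside the
#'   candidate list (null-pool material).
#' @param n_planted_mdgs,n_planted_edgs number of candidate genes given a
#'   planted methylation / expression effect. With
#'   `couple_promoter_expression = TRUE` the two sets coincide and must be
#'   equal in size; otherwise they are disjoint.
#' @param mutation_freq_range per-gene mutation frequency is drawn uniformly
#'   from this range, independently per cohort.
#' @param beta_mix two-component beta mixture for baseline methylation:
#'   list with `low_shape`, `high_shape` (each a length-2 shape pair).
#'   The per-site high-mode weight is drawn uniformly on \[0,1\].
#' @param driver_effect list with `fraction_of_sites_affected`,
#'   `methylation_shift` (signed, logit scale), `fraction_of_genes_affected`
#'   and `expression_log_fold` (signed, natural-log scale).
#' @param couple_promoter_expression logical; if `TRUE` the planted drivers
#'   act jointly on promoters and expression of the same target genes with
#'   coupled directions: half the affected targets are promoter
#'   hyper-methylated and down-regulated, half hypo-methylated and
#'   up-regulated.
#' @param promoter_sites_per_gene CpG sites per gene promoter.
#' @param missing_rate fraction of methylation entries set missing
#'   completely at random.
#' @param expr_log2_sd sample-level standard deviation of log2 expression.
#' @param seed integer master seed; identical seed and config reproduce
#'   identical output.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_cohorts()]
#' @export
sim_config <- function(n_cohorts = 3,
                       samples_per_cohort = 200,
                       n_sites = 20000,
                       n_genes = 2000,
                       n_candidate_drivers = 50,
                       n_passengers = 150,
                       n_planted_mdgs = 5,
                       n_planted_edgs = 5,
                       mutation_freq_range = c(0.05, 0.40),
                       beta_mix = list(low_shape = c(2, 8), high_shape = c(8, 2)),
                       driver_effect = list(fraction_of_sites_affected = 0.05,
                                            methylation_shift = 1.5,
                                            fraction_of_genes_affected = 0.05,
                                            expression_log_fold = -1),
                       couple_promoter_expression = FALSE,
                       promoter_sites_per_gene = 3,
                       missing_rate = 0.01,
                       expr_log2_sd = 1,
                       seed = 1L) {
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              samples_per_cohort = as.integer(samples_per_cohort),
              n_sites = as.integer(n_sites),
              n_genes = as.integer(n_genes),
              n_candidate_drivers = as.integer(n_candidate_drivers),
              n_passengers = as.integer(n_passengers),
              n_planted_mdgs = as.integer(n_planted_mdgs),
              n_planted_edgs = as.integer(n_planted_edgs),
              mutation_freq_range = as.numeric(mutation_freq_range),
              beta_mix = beta_mix,
              driver_effect = driver_effect,
              couple_promoter_expression = isTRUE(couple_promoter_expression),
              promoter_sites_per_gene = as.integer(promoter_sites_per_gene),
              missing_rate = as.numeric(missing_rate),
              expr_log2_sd = as.numeric(expr_log2_sd),
              seed = as.integer(seed))

  counts <- c("n_cohorts", "samples_per_cohort", "n_sites", "n_genes",
              "n_candidate_drivers", "promoter_sites_per_gene")
  for (nm in counts)
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stopf("'%s' must be a positive count", nm)
  for (nm in c("n_passengers", "n_planted_mdgs", "n_planted_edgs"))
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] < 0L)
      stopf("'%s' must be a non-negative count", nm)
  fr <- cfg$mutation_freq_range
  if (length(fr) != 2L || any(fr < 0) || any(fr > 1) || fr[1] > fr[2])
    stopf("'mutation_freq_range' must be an ordered pair within [0,1]")
  de <- cfg$driver_effect
  for (nm in c("fraction_of_sites_affected", "fraction_of_genes_affected"))
    if (is.null(de[[nm]]) || de[[nm]] < 0 || de[[nm]] > 1)
      stopf("driver_effect$%s must be a fraction in [0,1]", nm)
  for (nm in c("methylation_shift", "expression_log_fold"))
    if (is.null(de[[nm]]) || !is.finite(de[[nm]]))
      stopf("driver_effect$%s must be a finite number", nm)
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1)
    stopf("'missing_rate' must be a fraction in [0,1]")
  if (cfg$couple_promoter_expression && cfg$n_planted_mdgs != cfg$n_planted_edgs)
    stopf("with couple_promoter_expression the planted MDG and EDG sets coincide; counts must be equal")
  n_planted <- if (cfg$couple_promoter_expression) cfg$n_planted_mdgs else
    cfg$n_planted_mdgs + cfg$n_planted_edgs
  if (n_planted > cfg$n_candidate_drivers)
    stopf("planted drivers (%d) exceed candidate list size (%d)",
          n_planted, cfg$n_candidate_drivers)
  if (cfg$n_genes * cfg$promoter_sites_per_gene > cfg$n_sites)
    stopf("n_sites too small: %d promoter sites needed but only %d sites requested",
          cfg$n_genes * cfg$promoter_sites_per_gene, cfg$n_sites)
  # effects requested but unplaceable at this problem size
  if (cfg$n_planted_mdgs > 0 && !cfg$couple_promoter_expression &&
      de$fraction_of_sites_affected > 0 &&
      round(de$fraction_of_sites_affected * cfg$n_sites) < 1)
    stopf("n_sites too small to place the requested methylation effect")
  if ((cfg$n_planted_edgs > 0 || cfg$couple_promoter_expression) &&
      de$fraction_of_genes_affected > 0 &&
      round(de$fraction_of_genes_affected * cfg$n_genes) < 1)
    stopf("n_genes too small to place the requested expression effect")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d cohorts x %d samples; %d CpG sites, %d genes\n",
              x$n_cohorts, x$samples_per_cohort, x$n_sites, x$n_genes))
  cat(sprintf("  candidates: %d (planted MDGs %d, EDGs %d%s); passengers: %d\n",
              x$n_candidate_drivers, x$n_planted_mdgs, x$n_planted_edgs,
              if (x$couple_promoter_expression) ", coupled" else "",
              x$n_passengers))
  invisible(x)
}

.clip_beta <- function(b) pmin(pmax(b, 0.001), 0.999)

#' Simulate multi-cohort mutation, methylation and expression data
#'
#' Generates `n_cohorts` cohort bundles plus a ground-truth object. Baseline
#' beta values come from a per-site two-component beta mixture (high-mode
#' weight uniform per site), expression from a gene-level log-normal model,
#' and mutations from per-gene Bernoulli draws at frequencies uniform in
#' `mutation_freq_range`. Planted methylation drivers shift the beta values
#' of mutated samples at their affected sites on the logit scale (values are
#' clipped to \[0.001, 0.999\] before the logit, so shifted values stay in
#' \[0,1\]); planted expression drivers scale affected target genes by
#' `exp(expression_log_fold)` in mutated samples. Passengers and unaffected
#' candidates have no systematic effect. A single seeded RNG stream drives
#' the run; per-cohort sub-seeds are derived from it.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements
#'   \describe{
#'     \item{cohorts}{list of [cohort_bundle] objects, one per cohort.}
#'     \item{truth}{`sim_truth` object: data frame `genes` (gene, role,
#'       direction, n_affected_sites, n_affected_targets) plus named lists
#'       `affected_sites` and `affected_targets` holding the signed per-site
#'       logit shifts / per-target log folds.}
#'     \item{promoter_map}{data frame (gene, site_id, chrom, start, end)
#'       mapping genes to promoter CpG sites.}
#'   }
#' @export
simulate_cohorts <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  set.seed(cfg$seed)

  site_ids <- sprintf("cg%06d", seq_len(cfg$n_sites))
  gene_ids <- sprintf("TG%04d", seq_len(cfg$n_genes))
  cdg_ids <- sprintf("CDG%03d", seq_len(cfg$n_candidate_drivers))
  psg_ids <- if (cfg$n_passengers > 0) sprintf("PSG%03d", seq_len(cfg$n_passengers)) else character()
  mut_genes <- c(cdg_ids, psg_ids)

  k <- cfg$promoter_sites_per_gene
  promoter_map <- data.frame(
    gene = rep(gene_ids, each = k),
    site_id = site_ids[seq_len(cfg$n_genes * k)],
    chrom = "chrS",
    start = 1000L * (seq_len(cfg$n_genes * k) - 1L),
    end = 1000L * (seq_len(cfg$n_genes * k) - 1L) + 500L,
    stringsAsFactors = FALSE)

  de <- cfg$driver_effect
  mdg_genes <- cdg_ids[seq_len(cfg$n_planted_mdgs)]
  edg_genes <- if (cfg$couple_promoter_expression) mdg_genes else
    cdg_ids[cfg$n_planted_mdgs + seq_len(cfg$n_planted_edgs)]

  site_effects <- list()    # driver -> named numeric (site -> logit shift)
  target_effects <- list()  # driver -> named numeric (target gene -> log fold)

  if (cfg$couple_promoter_expression) {
    n_t <- round(de$fraction_of_genes_affected * cfg$n_genes)
    for (d in mdg_genes) {
      if (n_t < 1) break
      tg <- sample(gene_ids, n_t)
      half <- seq_len(ceiling(n_t / 2))
      # hyper-methylated promoter <-> down-regulated target, and vice versa
      lf <- setNames(rep(abs(de$expression_log_fold), n_t), tg)
      lf[half] <- -abs(de$expression_log_fold)
      sh_gene <- setNames(rep(-abs(de$methylation_shift), n_t), tg)
      sh_gene[half] <- abs(de$methylation_shift)
      pm_sites <- promoter_map$site_id[match(promoter_map$gene, tg, nomatch = 0L) > 0L]
      pm_gene <- promoter_map$gene[match(promoter_map$gene, tg, nomatch = 0L) > 0L]
      site_effects[[d]] <- setNames(sh_gene[pm_gene], pm_sites)
      target_effects[[d]] <- lf
    }
  } else {
    n_s <- round(de$fraction_of_sites_affected * cfg$n_sites)
    for (d in mdg_genes) {
      if (n_s < 1) break
      site_effects[[d]] <- setNames(rep(de$methylation_shift, n_s),
                                    sample(site_ids, n_s))
    }
    n_t <- round(de$fraction_of_genes_affected * cfg$n_genes)
    for (d in edg_genes) {
      if (n_t < 1) break
      target_effects[[d]] <- setNames(rep(de$expression_log_fold, n_t),
                                      sample(gene_ids, n_t))
    }
  }

  # gene-level baseline expression shared across cohorts
  mu_log2 <- setNames(runif(cfg$n_genes, 3, 8), gene_ids)
  cohort_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_cohorts)

  cohorts <- vector("list", cfg$n_cohorts)
  for (ci in seq_len(cfg$n_cohorts)) {
    set.seed(cohort_seeds[ci])
    cid <- sprintf("COH%02d", ci)
    samp <- sprintf("%s_S%03d", cid, seq_len(cfg$samples_per_cohort))
    ns <- cfg$samples_per_cohort

    freq <- runif(length(mut_genes), cfg$mutation_freq_range[1], cfg$mutation_freq_range[2])
    mut <- matrix(rbinom(ns * length(mut_genes), 1L, rep(freq, each = ns)),
                  nrow = ns, dimnames = list(samp, mut_genes))

    w <- runif(cfg$n_sites)  # per-site high-mode weight
    hi <- matrix(runif(cfg$n_sites * ns) < w, nrow = cfg$n_sites)
    bm <- cfg$beta_mix
    meth <- matrix(rbeta(cfg$n_sites * ns,
                         ifelse(hi, bm$high_shape[1], bm$low_shape[1]),
                         ifelse(hi, bm$high_shape[2], bm$low_shape[2])),
                   nrow = cfg$n_sites, dimnames = list(site_ids, samp))

    expr <- matrix(2 ^ (mu_log2 + rnorm(cfg$n_genes * ns, 0, cfg$expr_log2_sd)),
                   nrow = cfg$n_genes, dimnames = list(gene_ids, samp))

    for (d in names(site_effects)) {
      mu_idx <- which(mut[, d] == 1L)
      if (!length(mu_idx)) next
      sh <- site_effects[[d]]
      ridx <- match(names(sh), site_ids)
      meth[ridx, mu_idx] <- plogis(qlogis(.clip_beta(meth[ridx, mu_idx, drop = FALSE])) + sh)
    }
    for (d in names(target_effects)) {
      mu_idx <- which(mut[, d] == 1L)
      if (!length(mu_idx)) next
      lf <- target_effects[[d]]
      ridx <- match(names(lf), gene_ids)
      expr[ridx, mu_idx] <- expr[ridx, mu_idx, drop = FALSE] * exp(lf)
    }

    if (cfg$missing_rate > 0)
      meth[runif(length(meth)) < cfg$missing_rate] <- NA_real_

    cohorts[[ci]] <- cohort_bundle(cid, mutation = mut, methylation = meth,
                                   expression = expr)
  }
  names(cohorts) <- vapply(cohorts, function(b) b$cohort_id, character(1))

  dir_of <- function(g) {
    if (cfg$couple_promoter_expression && g %in% mdg_genes) return("both")
    if (g %in% mdg_genes) return(if (de$methylation_shift > 0) "hyper" else "hypo")
    NA_character_
  }
  edir_of <- function(g) {
    if (cfg$couple_promoter_expression && g %in% edg_genes) return("both")
    if (g %in% edg_genes) return(if (de$expression_log_fold > 0) "up" else "down")
    NA_character_
  }
  role <- ifelse(cdg_ids %in% mdg_genes & cdg_ids %in% edg_genes, "mdg+edg",
          ifelse(cdg_ids %in% mdg_genes, "mdg",
          ifelse(cdg_ids %in% edg_genes, "edg", "passenger_candidate")))
  genes_df <- data.frame(
    gene = c(cdg_ids, psg_ids),
    role = c(role, rep("passenger", length(psg_ids))),
    meth_direction = c(vapply(cdg_ids, dir_of, character(1)),
                       rep(NA_character_, length(psg_ids))),
    expr_direction = c(vapply(cdg_ids, edir_of, character(1)),
                       rep(NA_character_, length(psg_ids))),
    n_affected_sites = vapply(c(cdg_ids, psg_ids),
                              function(g) length(site_effects[[g]]), integer(1)),
    n_affected_targets = vapply(c(cdg_ids, psg_ids),
                                function(g) length(target_effects[[g]]), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)

  truth <- structure(list(genes = genes_df,
                          planted_mdgs = mdg_genes,
                          planted_edgs = edg_genes,
                          candidate_list = cdg_ids,
                          affected_sites = site_effects,
                          affected_targets = target_effects),
                     class = "sim_truth")
  list(cohorts = cohorts, truth = truth, promoter_map = promoter_map,
       config = cfg)
}

#' Write a simulated study to disk
#'
#' Writes each cohort in the TSV layout [load_cohort()] reads, plus the
#' ground truth (one row per mutated gene) and the promoter map as a
#' BED-like file.
#'
#' @param sim result of [simulate_cohorts()].
#' @param outdir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (b in sim$cohorts)
    files <- c(files, write_cohort(b, file.path(outdir, b$cohort_id)))
  tf <- file.path(outdir, "truth.tsv")
  data.table::fwrite(sim$truth$genes, tf, sep = "\t", na = "NA", quote = FALSE)
  pf <- file.path(outdir, "promoter_map.bed")
  data.table::fwrite(sim$promoter_map[, c("chrom", "start", "end", "gene", "site_id")],
                     pf, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(c(files, tf, pf))
}
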