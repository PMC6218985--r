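---
title: "Calling methylation and expression driver genes from pan-cancer cohorts"
author: "epidriver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling methylation and expression driver genes from pan-cancer cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidriver)
```

## The question and the model

Somatic mutations in some cancer genes do more than disable one pathway:
they reshape the tumor's whole epigenome or transcriptome, typically by
hitting a chromatin regulator or a gene that controls one. `epidriver`
implements a pan-cancer procedure that asks, for each candidate driver gene
(CDG) and each tumor cohort, whether the gene's mutation status is
associated with *genome-wide* DNA methylation changes (methylation driver
genes, MDGs) or gene expression changes (expression driver genes, EDGs),
and then aggregates the evidence across cohorts.

The per-cohort statistic is deliberately simple. For CDG $i$ in cohort $k$,
every CpG site is tested with a Wilcoxon rank-sum test comparing beta
values between mutated and wild-type samples — a nonparametric test chosen
because beta values are bounded in $[0,1]$, usually bimodal with mass near
0 and 1, and the mutated group is small (group sizes are extremely
unbalanced at mutation frequencies of roughly 5–40%). Two one-sided tests
at level $\alpha = 0.01$ per direction define the hyper-methylated site set
$S^+_{i,k}$ and the hypo-methylated set $S^-_{i,k}$; the statistic is the
count

$$n^m_{i,k} = |S^+_{i,k} \cup S^-_{i,k}|.$$

No site-level multiple-testing adjustment is applied, on purpose: the sites
are not individually claimed, only counted. The expression arm mirrors
this with Welch two-sample t-tests per gene at $\alpha = 0.05$, counting
up-regulated ($G^+$) and down-regulated ($G^-$) genes and excluding the
mutated gene from its own count.

## The empirical null: passenger mutations, not random labels

A count of 400 differential sites means nothing by itself — sparse mutated
groups and correlated sites inflate counts even without any driver effect.
The reference distribution is therefore built from *passenger* mutations:
per cohort, the genes mutated in at least 5 samples that are not on the
candidate list (capped at the 500 most frequently mutated per cohort, ties
broken lexicographically), each contributing its own genome-wide count
$n^m_{j_\text{null}}$. The per-cohort p-value is the inclusive tail
proportion

$$p_{i,k} = \frac{1}{|\text{pool}|} \sum_{j_\text{null}}
I\!\left(n^m_{i,k} \le n^m_{j_\text{null}}\right),$$

with no small-sample correction; an exact zero is reported with the
annotation `<1/|pool|`. A cohort-level effect is classified as genome-wide
hyper-methylation when $p_{i,k} < 0.05$ and $|S^+| > |S^-|$, hypo when
$p_{i,k} < 0.05$ and $|S^+| \le |S^-|$ (ties go to hypo), and none
otherwise.

An alternative null — randomly splitting samples into pseudo-mutated and
pseudo-wild-type groups at 5–40% in 1% steps, 10 repetitions each (360
counts per cohort, `random_split_null()`) — is provided as a sensitivity
check. On real tumor data passenger mutations carry residual genome-wide
association that random labels do not, which makes the passenger pool the
more honest (more conservative) null; on this package's synthetic data the
two constructions agree, and a test asserts exactly that.

## Pan-cancer aggregation

For gene $i$, let $A_i$ be the cohorts where it is mutated in at least 5
samples with the relevant data. The observed total
$\sum_{k \in A_i} n^m_{i,k}$ is compared with $B$ resampled sums of
$|A_i|$ pool values drawn uniformly with replacement ($B = 10^6$ by
default; zeros annotated `<1/B`). Resampled sums are drawn once per
$|A_i|$ stratum and shared by the genes in it — statistically identical
under the null, and much cheaper. Benjamini–Hochberg adjustment is then
applied *within* groups of genes sharing the same $|A_i|$, because genes
summing over different numbers of cohorts face different nulls; drivers
are genes with adjusted $p_i < 0.05$. The per-gene direction $D_i$ is
`both` when significant cohorts fall on both sides, one-sided otherwise,
and `NA` when no single cohort is individually significant (a gene can be
pan-cancer significant through consistent sub-threshold shifts).

## Downstream characterization

For a driver with cohort sets $T_i$ (methylation-significant) and $E_i$
(expression-significant), the package computes:

* **Common dysregulated targets** (`identify_common_targets()`): genes
  with expression p < 0.05 in *every* cohort of $T_i$; direction
  consistency is not required for membership.
* **Regulator enrichment** (`regulator_enrichment()`): upper-tail
  hypergeometric test of a chromatin-regulator list (e.g. the 720-gene
  EpiFactors-style list A, or the 21-gene master-regulator list B) among
  those targets, with both sets restricted to the measured universe first.
  The same operation serves for physical-interactor lists.
* **Promoter patterns** (`analyze_driver_patterns()`): per cohort in
  $T_i \cap E_i$, each target gene gets a promoter methylation call
  (strict majority vote over its CpG sites within 1,500 bp upstream of the
  TSS; ties and empty promoters are `none`) and an expression call. The
  four joint patterns `++`, `+-`, `-+`, `--` (methylation direction first)
  are each tested for excess with a hypergeometric test over the universe
  of genes with both promoter methylation and expression measured, and
  per-cohort p-values are combined with Fisher's method
  ($-2\sum\log p \sim \chi^2_{2m}$; zeros floored at $10^{-300}$ with a
  warning). Per-pattern counts sum to $|DM \cap DE|$ by construction.
* **Cross-cohort consistency** (`cross_cohort_consistency()`): for every
  cohort pair, a hypergeometric test of the overlap of the per-cohort DM
  (or DE) gene sets over the shared universe, reported as the median
  pairwise p-value; single-cohort drivers yield `NA`.

## The synthetic cohort generator

`simulate_cohorts()` produces the study conditions every test runs under.
Baseline beta values come from a per-site two-component beta mixture
(shapes (2,8) and (8,2); per-site high-mode weight uniform on $[0,1]$),
which reproduces the 450K-like enrichment near 0 and 1. Mutations are
Bernoulli per sample at per-gene frequencies drawn uniformly from 5–40%,
independently per cohort. Expression is log-normal per gene. Missing beta
values are placed completely at random (1% by default), matching a QC
regime that only constrains the missingness rate.

Planted effects define the ground truth:

* a planted MDG shifts the beta values of its mutated samples at a random
  5% of sites by +1.5 on the logit scale (values clipped to
  $[0.001, 0.999]$ before the logit, so results stay in $[0,1]$);
* a planted EDG multiplies a random 5% of target genes by
  $e^{-1}$ in mutated samples;
* with `couple_promoter_expression = TRUE` a planted driver acts on the
  *promoter sites* of its affected targets, half of them
  hyper-methylated-and-down-regulated, half hypo-and-up — the `+-`/`-+`
  signature the pattern stage is designed to detect.

The default effect sizes are calibration choices, not empirical claims:
real MDG effect sizes are not well characterized. One
seeded RNG stream drives a run (per-cohort sub-seeds are derived from it),
so identical configurations reproduce identical data.

Two sizing choices deserve a note. First, the default null pool uses 150
passenger genes per cohort (450 pool values at the 3-cohort default),
several times the candidate count: the pan-cancer p-values are read off
the tail of the empirical pool, and with a pool of only ~150 values the
far tail cannot be estimated, which makes small p-values anti-conservative
exactly where the grouped BH adjustment operates. A full pan-cancer
application makes the same trade on a larger scale: with a 500-gene
per-cohort cap over 20 tumor types the pool runs to several thousand
entries against a few hundred candidates. Second, test and example
problem sizes (up to 3 cohorts × 200 samples × 20,000 sites, resampling
depth $10^5$) are chosen so the full suite runs on a laptop-class single
core in minutes; they are desk-scale stand-ins for a 20-cohort study with
hundreds of thousands of CpG sites.

What the generator does *not* emulate — genomic coordinates, linkage
between neighboring CpGs, copy number, tumor purity, cohort-specific
mutational processes, and co-mutation structure beyond independent
Bernoulli draws — bounds what passing tests show: they validate the
statistical machinery and its calibration under the stated model, not
biological discovery on real tumors.

## Numerical and design decisions

* **Wilcoxon implementation.** Exact rank-sum p-values when both groups
  have ≤ 25 observations and no ties; otherwise the normal approximation
  with midrank tie correction and continuity correction (ties are common
  since beta values cluster near 0 and 1). The genome-wide counting step
  is vectorized: per-site ranks, missingness masks and tie terms are
  computed once per cohort (`site_rank_cache()`), after which the rank sum
  of any sample subset is a matrix product. Whether the original analysis
  used one two-sided test split by direction or two one-sided tests is not
  stated; this package uses two one-sided tests at 0.01 each, so a site
  can never be simultaneously hyper and hypo.
* **Welch rather than pooled-variance t-test** for expression, for
  robustness with unbalanced groups; degenerate zero-variance cases are
  defined explicitly (p = 1 with sign 0 when means agree, p = 0
  otherwise).
* **Missingness**: values are dropped per site, never imputed — safe under
  the strict >5% QC cap; sites whose mutated or wild-type group becomes
  empty are skipped and counted in `n_skipped`. QC missingness is computed
  over all methylation samples of a cohort (the alternative — after
  intersecting with mutation samples — is not what the QC wording
  implies, and the two filters commute either way).
* **Null-pool membership** keeps every (gene, cohort) pair, including the
  same gene selected in several cohorts: pairs are the natural unit of
  the pool's own definition, since each pair contributes an independent
  genome-wide count.
* **Resampling with replacement**, uniform over pool entries; with
  $B = 10^6$ far exceeding any pool, replacement is the only coherent
  reading.
* **Pattern-test universe**: genes with at least one surviving promoter
  CpG site and an expression measurement. Because enrichment p-values are
  meaningless without their universe, the universe is explicit and
  configurable here.
  The DM·DE overlap test treats DM and DE symmetrically.
* **Tie-breaking** is deterministic everywhere (lexicographic gene IDs at
  the null-pool cutoff; the `\le` branch of the direction rule assigns
  exact ties to hypo/down), so all results are invariant to input
  ordering.

## Known limitations

The method tests marginal association: co-mutation confounding (e.g. a
passenger whose carriers happen to overlap a true driver's carriers) is
not adjusted for; regression-based control is impractical under these
group sizes and these highly non-normal methylation distributions.
Per-cohort empirical p-values within one cohort are positively correlated
across genes (shared samples and sites), so goodness-of-fit statistics on
them are wider than iid theory suggests even when marginal calibration is
exact. Finally, with candidate lists supplied by the user, everything
downstream is conditional on that list: the package does not discover
candidates.

## A worked example

```{r example, eval = FALSE}
library(epidriver)

sim <- simulate_cohorts(sim_config(seed = 1))
res <- call_driver_genes(sim$cohorts, sim$truth$candidate_list,
                         modality = "methylation", B = 1e5, seed = 1)
res
subset(res$calls, is_driver,
       select = c(gene, n_cohorts_eligible, n_signif, p_label, p_adj, direction))

pat_sim <- simulate_cohorts(sim_config(
  n_cohorts = 2, samples_per_cohort = 150, n_sites = 3000, n_genes = 1000,
  n_candidate_drivers = 5, n_passengers = 0, n_planted_mdgs = 1,
  n_planted_edgs = 1, couple_promoter_expression = TRUE, seed = 3))
analyze_driver_patterns(pat_sim$cohorts, pat_sim$truth$planted_mdgs,
                        pat_sim$promoter_map)
```
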