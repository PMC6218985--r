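# Site- and gene-level two-group association statistics.
#
# The per-cohort test statistic of the pipeline is a genome-wide count:
# the number of CpG sites whose beta values differ between mutated and
# wild-type samples of a gene (Wilcoxon rank-sum, one-sided at alpha in
# each direction), or the number of genes whose expression differs (Welch
# t-test). Because the counting step is run for every candidate and every
# null-pool gene, the Wilcoxon machinery is vectorized: per-site ranks,
# missingness masks and tie corrections are computed once per cohort and
# reused for every gene via matrix products.

#' One-sided Wilcoxon rank-sum tests for a single CpG site
#'
#' Compares beta values of mutated versus wild-type samples and returns
#' the one-sided p-values in both directions. Missing values are dropped.
#' When both groups have at most 25 observations and the data are free of
#' ties, the exact rank-sum distribution is used; otherwise the normal
#' approximation with midrank tie correction and continuity correction.
#'
#' @param mutated,wildtype numeric vectors of beta values.
#' @return named numeric vector `c(p_greater, p_less)`: evidence that the
#'   mutated group is stochastically greater (hyper) resp. smaller (hypo).
#' @export
#' @examples
#' wilcoxon_site_test(c(0.9, 0.8, 0.85), c(0.1, 0.2, 0.15, 0.05))  # 1/35
wilcoxon_site_test <- function(mutated, wildtype) {
  x <- mutated[!is.na(mutated)]
  y <- wildtype[!is.na(wildtype)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L)
    stopf("wilcoxon_site_test: a group is empty after removing missing values")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (n1 <= 25L && n2 <= 25L && !ties) {
    p_g <- pwilcox(U - 1, n1, n2, lower.tail = FALSE)  # P(U >= u)
    p_l <- pwilcox(U, n1, n2)                          # P(U <= u)
  } else {
    n <- n1 + n2
    tie_term <- if (ties) {
      tt <- table(c(x, y)); tt <- tt[tt > 1L]; sum(tt^3 - tt)
    } else 0
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sig2 <= 0) return(c(p_greater = 1, p_less = 1))  # all values tied
    sd <- sqrt(sig2)
    p_g <- pnorm((U - 0.5 - mu) / sd, lower.tail = FALSE)
    p_l <- pnorm((U + 0.5 - mu) / sd)
  }
  c(p_greater = p_g, p_less = p_l)
}

#' Precompute per-cohort rank structures for vectorized site tests
#'
#' Computes, per CpG site, the midranks of the non-missing beta values, a
#' missingness mask, the number of non-missing samples and the tie
#' correction term \eqn{\sum_t (t^3 - t)}. With these in hand, the rank sum
#' of any sample subset is a single matrix product, so genome-wide counts
#' for hundreds of genes reduce to a few dense multiplications.
#'
#' @param meth sites x samples beta matrix (NA allowed).
#' @return an object of class `site_rank_cache`.
#' @export
site_rank_cache <- function(meth) {
  stopifnot(is.matrix(meth))
  ns <- nrow(meth)
  M <- matrix(0, ns, ncol(meth), dimnames = dimnames(meth))
  R <- M
  tie <- numeric(ns)
  for (s in seq_len(ns)) {
    ok <- !is.na(meth[s, ])
    v <- meth[s, ok]
    M[s, ok] <- 1
    R[s, ok] <- rank(v)
    if (anyDuplicated(v)) {
      tt <- table(v); tt <- tt[tt > 1L]
      tie[s] <- sum(tt^3 - tt)
    }
  }
  structure(list(R = R, M = M, n = rowSums(M), tie = tie,
                 samples = colnames(meth), sites = rownames(meth)),
            class = "site_rank_cache")
}

# One-sided normal-approximation p-values for every (site, group) pair.
# groups: samples x K 0/1 matrix aligned with cache$samples.
# Returns list(p_greater, p_less, valid), each sites x K.
.site_p_matrices <- function(cache, groups) {
  stopifnot(inherits(cache, "site_rank_cache"),
            nrow(groups) == length(cache$samples))
  n1 <- cache$M %*% groups
  W <- cache$R %*% groups
  n2 <- cache$n - n1
  U <- W - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  denom <- cache$n * (cache$n - 1)
  denom[denom == 0] <- Inf
  sig2 <- n1 * n2 / 12 * ((cache$n + 1) - cache$tie / denom)
  valid <- n1 > 0 & n2 > 0 & sig2 > 0
  sd <- sqrt(pmax(sig2, .Machine$double.eps))
  list(p_greater = pnorm((U - 0.5 - mu) / sd, lower.tail = FALSE),
       p_less = pnorm((U + 0.5 - mu) / sd),
       valid = valid)
}

# Differential-site counts for each column of a 0/1 group matrix.
.counts_from_groups <- function(cache, groups, alpha_site) {
  pm <- .site_p_matrices(cache, groups)
  n_plus <- colSums(pm$p_greater < alpha_site & pm$valid)
  n_minus <- colSums(pm$p_less < alpha_site & pm$valid)
  data.frame(n_plus = as.integer(n_plus), n_minus = as.integer(n_minus),
             n_m = as.integer(n_plus + n_minus),
             n_skipped = as.integer(colSums(!pm$valid)),
             row.names = NULL)
}

#' Genome-wide differential-methylation counts for a set of genes
#'
#' For every gene, compares beta values of mutated versus wild-type samples
#' at every CpG site with one-sided Wilcoxon tests at `alpha_site` per
#' direction (no site-level multiple-testing adjustment: the count itself is
#' the statistic, not the site identities). `n_plus` is the number of
#' significantly hyper-methylated sites (the set S+), `n_minus` the
#' hypo-methylated count (S-); the two sets are disjoint, so
#' `n_m = n_plus + n_minus`. Cohorts whose mutated and wild-type groups both
#' have at most 25 samples are tested per site with the exact
#' [wilcoxon_site_test()]; larger cohorts use the vectorized normal
#' approximation. Sites with an empty group after missing-value removal are
#' skipped and counted in `n_skipped`.
#'
#' @param bundle a [cohort_bundle()].
#' @param genes character vector of genes in the mutation matrix.
#' @param alpha_site per-direction site-level significance level.
#' @param cache optional [site_rank_cache()] for the bundle's methylation
#'   matrix restricted to the methylation-analysis samples.
#' @return data frame (gene, cohort, modality, n_plus, n_minus, n_m,
#'   n_mutated, n_skipped).
#' @export
diff_meth_counts <- function(bundle, genes, alpha_site = 0.01, cache = NULL) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  samples <- modality_samples(bundle, "methylation")
  if (!length(samples)) stopf("cohort '%s' has no methylation-analysis samples",
                              bundle$cohort_id)
  missing_genes <- setdiff(genes, colnames(bundle$mutation))
  if (length(missing_genes))
    stopf("genes absent from mutation matrix: %s",
          paste(head(missing_genes, 5), collapse = ", "))
  mut <- bundle$mutation[samples, genes, drop = FALSE]
  n1 <- colSums(mut)
  if (any(n1 == 0L))
    stopf("gene(s) mutated in no sample with methylation data: %s",
          paste(head(genes[n1 == 0L], 5), collapse = ", "))
  n <- length(samples)
  exact <- n1 <= 25L & (n - n1) <= 25L

  out <- data.frame(gene = genes, cohort = bundle$cohort_id,
                    modality = "methylation",
                    n_plus = NA_integer_, n_minus = NA_integer_,
                    n_m = NA_integer_, n_mutated = as.integer(n1),
                    n_skipped = 0L, stringsAsFactors = FALSE)
  meth <- bundle$methylation[, samples, drop = FALSE]
  if (!is.null(cache) && !identical(cache$samples, samples)) cache <- NULL
  if (any(!exact)) {
    if (is.null(cache)) cache <- site_rank_cache(meth)
    cnt <- .counts_from_groups(cache, mut[, !exact, drop = FALSE], alpha_site)
    out[!exact, c("n_plus", "n_minus", "n_m", "n_skipped")] <- cnt
  }
  for (g in genes[exact]) {
    is_mut <- mut[, g] == 1L
    np <- 0L; nm <- 0L; nsk <- 0L
    for (s in seq_len(nrow(meth))) {
      x <- meth[s, is_mut]; y <- meth[s, !is_mut]
      if (all(is.na(x)) || all(is.na(y))) { nsk <- nsk + 1L; next }
      p <- wilcoxon_site_test(x, y)
      if (p[["p_greater"]] < alpha_site) np <- np + 1L
      else if (p[["p_less"]] < alpha_site) nm <- nm + 1L
    }
    out[out$gene == g, c("n_plus", "n_minus", "n_m", "n_skipped")] <-
      list(np, nm, np + nm, nsk)
  }
  out
}

#' Differential-methylation count for one gene
#'
#' Single-gene convenience wrapper around [diff_meth_counts()].
#'
#' @inheritParams diff_meth_counts
#' @param gene a single gene identifier.
#' @return one-row data frame as in [diff_meth_counts()].
#' @export
diff_methylation_count <- function(bundle, gene, alpha_site = 0.01, cache = NULL) {
  stopifnot(length(gene) == 1L)
  diff_meth_counts(bundle, gene, alpha_site = alpha_site, cache = cache)
}

#' Per-site direction calls for one gene
#'
#' Classifies every CpG site as `hyper`, `hypo` or `none` for the given
#' gene's mutation status, using the same one-sided tests as
#' [diff_meth_counts()]. Used by the promoter-pattern stage.
#'
#' @inheritParams diff_methylation_count
#' @return named character vector over sites.
#' @export
site_direction_calls <- function(bundle, gene, alpha_site = 0.01, cache = NULL) {
  stopifnot(length(gene) == 1L)
  samples <- modality_samples(bundle, "methylation")
  meth <- bundle$methylation[, samples, drop = FALSE]
  is_mut <- bundle$mutation[samples, gene] == 1L
  if (!any(is_mut)) stopf("gene '%s' mutated in no methylation sample", gene)
  n1 <- sum(is_mut); n2 <- sum(!is_mut)
  calls <- rep("none", nrow(meth))
  names(calls) <- rownames(meth)
  if (n1 <= 25L && n2 <= 25L) {
    for (s in seq_len(nrow(meth))) {
      x <- meth[s, is_mut]; y <- meth[s, !is_mut]
      if (all(is.na(x)) || all(is.na(y))) next
      p <- wilcoxon_site_test(x, y)
      if (p[["p_greater"]] < alpha_site) calls[s] <- "hyper"
      else if (p[["p_less"]] < alpha_site) calls[s] <- "hypo"
    }
  } else {
    if (!is.null(cache) && !identical(cache$samples, samples)) cache <- NULL
    if (is.null(cache)) cache <- site_rank_cache(meth)
    pm <- .site_p_matrices(cache, matrix(as.numeric(is_mut), ncol = 1))
    calls[pm$p_greater[, 1] < alpha_site & pm$valid[, 1]] <- "hyper"
    calls[pm$p_less[, 1] < alpha_site & pm$valid[, 1]] <- "hypo"
  }
  calls
}

#' Welch two-sample t-test for one gene's expression
#'
#' Two-sided Welch (unequal-variance) t-test of expression in mutated
#' versus wild-type samples, with the direction sign of the mean
#' difference. Degenerate inputs are handled explicitly: zero variance in
#' both groups gives p = 1 and sign 0 when the means are equal, p = 0 with
#' the sign of the difference otherwise.
#'
#' @param mutated,wildtype numeric vectors (each of length >= 2).
#' @return named numeric vector `c(p, sign)`.
#' @export
#' @examples
#' ttest_gene_expression(c(1, 2, 3), c(4, 5, 6))
ttest_gene_expression <- function(mutated, wildtype) {
  x <- mutated[!is.na(mutated)]
  y <- wildtype[!is.na(wildtype)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L)
    stopf("ttest_gene_expression: both groups need >= 2 values")
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0) {
    if (m1 == m2) return(c(p = 1, sign = 0))
    return(c(p = 0, sign = sign(m1 - m2)))
  }
  se2 <- v1 / n1 + v2 / n2
  tval <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  c(p = 2 * pt(-abs(tval), df), sign = sign(m1 - m2))
}

# Vectorized Welch t-tests: expression rows vs one sample split.
# Returns list(p, sign), each a vector over rows of expr.
.expr_ttest_one <- function(expr, is_mut) {
  n1 <- sum(is_mut); n2 <- sum(!is_mut)
  if (n1 < 2L || n2 < 2L)
    stopf("expression test needs >= 2 samples in both groups (got %d/%d)", n1, n2)
  x <- expr[, is_mut, drop = FALSE]
  y <- expr[, !is_mut, drop = FALSE]
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- (rowSums(x^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (rowSums(y^2) - n2 * m2^2) / (n2 - 1)
  v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
  se2 <- v1 / n1 + v2 / n2
  p <- rep(1, nrow(expr)); sg <- sign(m1 - m2)
  deg <- se2 == 0
  p[deg & m1 != m2] <- 0
  sg[deg & m1 == m2] <- 0
  ok <- !deg
  if (any(ok)) {
    tval <- (m1[ok] - m2[ok]) / sqrt(se2[ok])
    df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
    p[ok] <- 2 * pt(-abs(tval), df)
  }
  list(p = p, sign = sg)
}

#' Genome-wide differential-expression counts for a set of genes
#'
#' Expression analogue of [diff_meth_counts()]: for every mutated gene,
#' Welch t-tests compare each expression gene between mutated and wild-type
#' samples; `n_plus` counts significantly up-regulated genes (G+, p <
#' `alpha_gene` and positive mean difference), `n_minus` down-regulated
#' ones (G-). The mutated gene itself is excluded from its own counts.
#'
#' @param bundle a [cohort_bundle()].
#' @param genes mutated genes to test.
#' @param alpha_gene two-sided gene-level significance level.
#' @return data frame (gene, cohort, modality, n_plus, n_minus, n_m,
#'   n_mutated, n_skipped).
#' @export
diff_expr_counts <- function(bundle, genes, alpha_gene = 0.05) {
  stopifnot(inherits(bundle, "cohort_bundle"), !is.null(bundle$expression))
  samples <- modality_samples(bundle, "expression")
  if (!length(samples)) stopf("cohort '%s' has no expression-analysis samples",
                              bundle$cohort_id)
  missing_genes <- setdiff(genes, colnames(bundle$mutation))
  if (length(missing_genes))
    stopf("genes absent from mutation matrix: %s",
          paste(head(missing_genes, 5), collapse = ", "))
  expr <- bundle$expression[, samples, drop = FALSE]
  out <- data.frame(gene = genes, cohort = bundle$cohort_id,
                    modality = "expression",
                    n_plus = NA_integer_, n_minus = NA_integer_,
                    n_m = NA_integer_, n_mutated = NA_integer_,
                    n_skipped = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    g <- genes[i]
    is_mut <- bundle$mutation[samples, g] == 1L
    if (!any(is_mut))
      stopf("gene '%s' mutated in no sample with expression data", g)
    tt <- .expr_ttest_one(expr, is_mut)
    self <- rownames(expr) == g
    up <- sum(tt$p < alpha_gene & tt$sign > 0 & !self)
    down <- sum(tt$p < alpha_gene & tt$sign < 0 & !self)
    out[i, c("n_plus", "n_minus", "n_m", "n_mutated")] <-
      list(as.integer(up), as.integer(down), as.integer(up + down),
           as.integer(sum(is_mut)))
  }
  out
}

#' Differential-expression count for one gene
#'
#' Single-gene wrapper around [diff_expr_counts()].
#'
#' @inheritParams diff_expr_counts
#' @param gene a single gene identifier.
#' @return one-row data frame.
#' @export
diff_expression_count <- function(bundle, gene, alpha_gene = 0.05) {
  stopifnot(length(gene) == 1L)
  diff_expr_counts(bundle, gene, alpha_gene = alpha_gene)
}

#' Per-gene expression direction calls for one driver
#'
#' Classifies every expression gene as `up`, `down` or `none` under the
#' driver's mutation status (two-sided Welch test at `alpha_gene`, split by
#' the sign of the mean difference). The driver itself is set to `none`.
#'
#' @inheritParams diff_expression_count
#' @return named character vector over expression genes; the per-gene
#'   two-sided p-values are attached as attribute `p`.
#' @export
expression_direction_calls <- function(bundle, gene, alpha_gene = 0.05) {
  stopifnot(length(gene) == 1L)
  samples <- modality_samples(bundle, "expression")
  expr <- bundle$expression[, samples, drop = FALSE]
  is_mut <- bundle$mutation[samples, gene] == 1L
  if (!any(is_mut)) stopf("gene '%s' mutated in no expression sample", gene)
  tt <- .expr_ttest_one(expr, is_mut)
  calls <- rep("none", nrow(expr))
  names(calls) <- rownames(expr)
  calls[tt$p < alpha_gene & tt$sign > 0] <- "up"
  calls[tt$p < alpha_gene & tt$sign < 0] <- "down"
  calls[names(calls) == gene] <- "none"
  attr(calls, "p") <- setNames(tt$p, rownames(expr))
  calls
}
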