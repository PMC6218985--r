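# Shared fixtures and independent oracles used across the test files.

# Small deterministic cohort bundle built entirely in code.
make_toy_bundle <- function(n_samples = 12, n_sites = 30, n_genes = 8,
                            n_mut_genes = 3, seed = 42, cohort_id = "TOY") {
  set.seed(seed)
  samp <- sprintf("S%02d", seq_len(n_samples))
  sites <- sprintf("cg%03d", seq_len(n_sites))
  genes <- sprintf("G%02d", seq_len(n_genes))
  mgenes <- sprintf("M%02d", seq_len(n_mut_genes))
  mut <- matrix(rbinom(n_samples * n_mut_genes, 1, 0.3),
                n_samples, dimnames = list(samp, mgenes))
  mut[1, ] <- 1L  # every gene mutated at least once
  meth <- matrix(rbeta(n_sites * n_samples, 2, 2),
                 n_sites, dimnames = list(sites, samp))
  expr <- matrix(2 ^ rnorm(n_genes * n_samples, 6, 1),
                 n_genes, dimnames = list(genes, samp))
  cohort_bundle(cohort_id, mut, meth, expr)
}

# Exact Wilcoxon oracle: enumerate all C(n1+n2, n1) assignments of the
# pooled midranks to group 1 and compare rank sums. Handles ties.
wilcoxon_enum_oracle <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(n, n1)
  sums <- colSums(matrix(r[combos], nrow = n1))
  c(p_greater = mean(sums >= obs), p_less = mean(sums <= obs))
}

# Brute-force BH step-up oracle: adj_i = min_{j >= i} p_(j) * m / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# Exact hypergeometric upper tail by direct combinatorial enumeration.
hypergeom_enum_oracle <- function(N, K, n, k) {
  kk <- max(0, K + n - N):min(K, n)
  probs <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  sum(probs[kk >= k])
}
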