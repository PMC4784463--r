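# Small fixtures built in code, shared across test files.

# tiny deterministic case-control dataset with one strong causal SNP
toy_dataset <- function(n = 600, n_markers = 6, or = 2.5, seed = 101) {
  set.seed(seed)
  g <- matrix(rbinom(n * n_markers, 2L, 0.3), n, n_markers)
  y <- simulate_phenotype(g, 1L, or, baseline_prevalence = 0.4)
  genotype_dataset(g, y, truth = 1L, phenotype_type = "binary")
}

# scaled-down scenario spec for fast end-to-end runs
small_spec <- function(scenario = 1, scheme = 2, seed = 1, ...) {
  scenario_spec(scenario, scheme, n_cases = 300, n_controls = 300,
                population_size = 15000, seed = seed, ...)
}

# independent step-up implementation used as the BH oracle
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- max(c(0L, which(ps <= seq_len(m) * q / m)))
  if (k == 0L) integer(0) else sort(ord[seq_len(k)])
}

# all permutations of 1:n (recursive, used for the BH ordering oracle)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# brute-force G2 evaluation used as the statistic oracle
g2_oracle <- function(o) {
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  terms <- o * log(o / e)
  terms[o == 0] <- 0
  2 * sum(terms)
}
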