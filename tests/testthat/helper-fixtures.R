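## shared fixtures: tiny parameter sets and state-space helpers

tiny_params <- function(...) {
  sim_params(K = 2e3, generations = 3, ...)
}

## pair-state index from two explicit haplotypes (selection case)
ps <- function(h1, h2) pair_state(h1, h2, selection = TRUE)

## random genotype as a vector of pair-state indices
random_genotype <- function(n_pairs, selection = TRUE) {
  n_states <- if (selection) 10 else 3
  sample.int(n_states, n_pairs, replace = TRUE)
}

## brute-force two-population Nei GST, written as an explicit per-locus
## loop independent of the package implementation
brute_force_gst <- function(p1, p2, size1, size2) {
  num <- 0
  den <- 0
  hs <- 0
  for (j in seq_along(p1)) {
    pj <- (size1 * p1[j] + size2 * p2[j]) / (size1 + size2)
    hs <- hs + (2 * p1[j] * (1 - p1[j]) + 2 * p2[j] * (1 - p2[j])) / 2
    den <- den + 2 * pj * (1 - pj)
  }
  hs <- hs / length(p1)
  den <- den / length(p1)
  num <- den - hs
  if (den == 0) return(NA_real_)
  num / den
}

## marginal frequency of allele 1 at the neutral (or selected) locus of
## pair `j` in a haplotype probability vector returned by gamete_pool()
pool_allele_freq <- function(pool, j, locus = c("neutral", "selected")) {
  locus <- match.arg(locus)
  codes <- attr(pool, "hap_codes")
  d <- codes[, j]
  allele <- if (locus == "neutral") d %/% 2 else d %% 2
  sum(pool[allele == 1])
}
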