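## ------------------------------------------------------------------------
## Population-genetic summaries: expected heterozygosity, Nei-style FST on
## neutral loci and FSTQ on selected loci, time-course increments, and
## FST-FSTQ rank correlations.
## ------------------------------------------------------------------------

#' Expected heterozygosity of a biallelic locus
#'
#' @param p Allele frequency (or vector of frequencies), in `[0, 1]`.
#' @return `2 * p * (1 - p)`.
#' @export
#' @examples
#' expected_heterozygosity(c(0.5, 0, 0.4))
expected_heterozygosity <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  2 * p * (1 - p)
}

#' Nei-style FST between two populations from allele frequencies
#'
#' Differentiation is `FST = (HT - HS) / HT`, where `HS` is the expected
#' heterozygosity `2p(1-p)` averaged over loci and over the two
#' populations, and `HT` the expected heterozygosity of the pooled
#' population, averaged over loci.  Pooled allele frequencies weight each
#' population by its census size (total number of alleles); loci are
#' averaged on the heterozygosities before the ratio is formed.
#'
#' @param p1,p2 Per-locus allele frequencies in populations 1 and 2
#'   (equal-length vectors).
#' @param size1,size2 Census sizes used to weight the pooled frequency
#'   (real-valued densities are fine).  Defaults give equal weights.
#' @return A list with `fst`, `h_t` and `h_s`.  `fst` is `NA` (undefined)
#'   when `HT` is zero, i.e. both populations are monomorphic for the
#'   same alleles, or when either census is zero.
#' @export
#' @examples
#' fst_nei(0.2, 0.6)  # HS = 0.4, HT = 0.48, FST = 1/6
fst_nei <- function(p1, p2, size1 = 1, size2 = 1) {
  stopifnot(length(p1) == length(p2), size1 >= 0, size2 >= 0)
  if (length(p1) == 0 || size1 + size2 == 0 || size1 == 0 || size2 == 0) {
    return(list(fst = NA_real_, h_t = NA_real_, h_s = NA_real_))
  }
  pbar <- (size1 * p1 + size2 * p2) / (size1 + size2)
  h_s <- mean((expected_heterozygosity(p1) + expected_heterozygosity(p2)) / 2)
  h_t <- mean(expected_heterozygosity(pbar))
  fst <- if (h_t > 0) (h_t - h_s) / h_t else NA_real_
  list(fst = fst, h_t = h_t, h_s = h_s)
}

#' Per-locus allele frequencies of a genotype-space state
#'
#' Frequencies of allele 1 at each neutral (and, with selection, each
#' selected) locus, computed from genotype tallies or densities by
#' counting alleles; in the deterministic regime counts are real-valued
#' densities and frequencies are density-weighted.
#'
#' @param w Genotype tallies/densities over the genotype space of `model`.
#' @param model A [sim_model()] object.
#' @return List with `neutral` (length `n_loci`) and `selected` (length
#'   `s_loci`, possibly empty) frequency vectors and the total census
#'   `size`; frequencies are `NA` when the census is zero.
#' @export
locus_frequencies <- function(w, model) {
  space <- model$space
  b <- space$basis
  tot <- sum(w)
  n <- space$n_pairs
  p_neu <- rep(NA_real_, n)
  p_sel <- if (b$selection) rep(NA_real_, n) else numeric(0)
  if (tot > 0) {
    for (j in seq_len(n)) {
      m <- pair_marginal(w, space, j)
      p_neu[j] <- sum(m * b$neu_count) / (2 * tot)
      if (b$selection) p_sel[j] <- sum(m * b$sel_count) / (2 * tot)
    }
    ## guard against floating-point drift just outside [0, 1] when the
    ## counts are real-valued densities
    p_neu <- pmin(pmax(p_neu, 0), 1)
    p_sel <- pmin(pmax(p_sel, 0), 1)
  }
  list(neutral = p_neu, selected = p_sel, size = tot)
}

#' FST and FSTQ between two genotype-space states
#'
#' @param w1,w2 Genotype tallies/densities of the two populations.
#' @param model A [sim_model()] object.
#' @return List with `fst`, `fstq` (NA when no selected loci), `h_t`,
#'   `h_s` (neutral-locus heterozygosities) and the two censuses.
#' @export
fst_from_states <- function(w1, w2, model) {
  f1 <- locus_frequencies(w1, model)
  f2 <- locus_frequencies(w2, model)
  neu <- fst_nei(f1$neutral, f2$neutral, f1$size, f2$size)
  fstq <- NA_real_
  if (length(f1$selected) > 0) {
    fstq <- fst_nei(f1$selected, f2$selected, f1$size, f2$size)$fst
  }
  list(fst = neu$fst, fstq = fstq, h_t = neu$h_t, h_s = neu$h_s,
       census_1 = f1$size, census_2 = f2$size)
}

#' Increment of FST along a trajectory
#'
#' Change in differentiation between the first and last recorded sexual
#' generation; negative values indicate migration dominating, positive
#' values drift.
#'
#' @param trajectory Numeric vector of FST values, or a data frame with
#'   an `fst` column ordered by generation.
#' @return `FST(last) - FST(first)`.
#' @export
delta_fst <- function(trajectory) {
  if (is.data.frame(trajectory)) trajectory <- trajectory$fst
  stopifnot(length(trajectory) >= 2)
  trajectory[length(trajectory)] - trajectory[1]
}

#' Rank correlation between replicate-level FST and FSTQ
#'
#' Kendall's tau and Spearman's rho over per-replicate (FST, FSTQ) pairs
#' within one parameter combination.
#'
#' @param fst,fstq Equal-length numeric vectors (one value per
#'   replicate), or `fst` may be a data frame with `fst` and `fstq`
#'   columns.
#' @return List with `tau`, `rho` and `n`.  Correlations are `NA`
#'   (undefined) when either margin has zero variance.
#' @export
fst_fstq_association <- function(fst, fstq = NULL) {
  if (is.data.frame(fst)) {
    fstq <- fst$fstq
    fst <- fst$fst
  }
  keep <- is.finite(fst) & is.finite(fstq)
  fst <- fst[keep]
  fstq <- fstq[keep]
  if (length(fst) < 3) stop("need at least 3 replicate pairs")
  if (stats::sd(fst) == 0 || stats::sd(fstq) == 0) {
    return(list(tau = NA_real_, rho = NA_real_, n = length(fst)))
  }
  list(tau = cor(fst, fstq, method = "kendall"),
       rho = cor(fst, fstq, method = "spearman"),
       n = length(fst))
}

#' Mean trajectory of a statistic across replicates
#'
#' Averages a per-generation statistic over replicates within each
#' parameter combination of a tidy results table, dropping replicates
#' flagged as extinct.
#'
#' @param results Tibble from [run_experiment()].
#' @param var Column to average (e.g. `"fst"`, `"fstq"`).
#' @return Tibble with one row per generation (and per combination, if
#'   several are present) and columns `y`, `mean`, `n_replicates`.
#' @export
mean_trajectory <- function(results, var = "fst") {
  stopifnot(var %in% names(results))
  keys <- intersect(c("preset", "K", "r", "M", "F", "delta", "c", "bank"),
                    names(results))
  res <- results[!results$extinct_flag, , drop = FALSE]
  dplyr::summarise(
    dplyr::group_by(res, dplyr::across(dplyr::all_of(c(keys, "y")))),
    mean = mean(.data[[var]], na.rm = TRUE),
    n_replicates = dplyr::n(),
    .groups = "drop"
  )
}

#' First generation at which a trajectory reaches its plateau
#'
#' The plateau is estimated as the mean of the trajectory over its last
#' `tail_frac` of generations; the function reports the first generation
#' at which the trajectory attains `level` times that plateau.
#'
#' @param y Generation numbers (ascending).
#' @param value Trajectory values (e.g. mean FSTQ per generation).
#' @param level Fraction of the plateau to attain (default 0.95).
#' @param tail_frac Fraction of the trajectory tail used to estimate the
#'   plateau.
#' @return List with `generation` (first attaining the level) and
#'   `plateau`.
#' @export
plateau_generation <- function(y, value, level = 0.95, tail_frac = 0.1) {
  stopifnot(length(y) == length(value), length(y) >= 2,
            !is.unsorted(y))
  ntail <- max(2L, ceiling(tail_frac * length(y)))
  plateau <- mean(value[seq(length(value) - ntail + 1L, length(value))],
                  na.rm = TRUE)
  hit <- which(value >= level * plateau)
  list(generation = if (length(hit)) y[hit[1]] else NA_real_,
       plateau = plateau)
}
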