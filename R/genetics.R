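## ------------------------------------------------------------------------
## Per-pair genetic basis
##
## Each individual carries n locus pairs.  A pair is one biallelic neutral
## marker locus physically linked (recombination fraction `recomb`) to one
## biallelic locus under selection; pairs assort independently of each
## other.  With selection a single-pair haplotype is one of four allele
## combinations and an (unordered, phase-preserving) pair diplotype is one
## of 10 states; without selected loci a pair collapses to one neutral
## locus with 2 haplotypes and 3 diplotype states.
## ------------------------------------------------------------------------

#' Build the single-pair genetic basis
#'
#' Enumerates single-pair haplotypes and unordered pair diplotypes, the
#' gamete transmission matrix for a given within-pair recombination
#' fraction, per-state allele counts and the additive fitness factor of
#' each state.
#'
#' @param selection Logical; do pairs carry a selected locus (10 diplotype
#'   states) or only the neutral marker (3 states)?
#' @param recomb Within-pair recombination fraction, in `[0, 0.5]`.
#'   Ignored when `selection = FALSE`.
#' @return An object of class `"pair_basis"`: a list with the haplotype
#'   allele table `hap`, diplotype state table `states`, state lookup `S2`
#'   (haplotype pair -> state), gamete transmission matrix `Tm`
#'   (`n_hap x n_state`), neutral/selected allele-one counts per state and
#'   the per-state fitness factor `kfac` (theta of a state in locality 1
#'   equals `delta * kfac`).
#' @keywords internal
pair_basis <- function(selection = TRUE, recomb = 0.5) {
  if (recomb < 0 || recomb > 0.5) {
    stop("recombination fraction must lie in [0, 0.5], got ", recomb)
  }
  if (selection) {
    ## haplotype code h = 2*neutral + selected, 0-based
    hap <- cbind(neutral = c(0L, 0L, 1L, 1L), selected = c(0L, 1L, 0L, 1L))
  } else {
    hap <- cbind(neutral = c(0L, 1L))
  }
  n_hap <- nrow(hap)
  states <- NULL
  for (a in seq_len(n_hap)) {
    for (b in a:n_hap) states <- rbind(states, c(a, b))
  }
  colnames(states) <- c("h1", "h2")
  n_state <- nrow(states)
  S2 <- matrix(0L, n_hap, n_hap)
  for (k in seq_len(n_state)) {
    S2[states[k, 1], states[k, 2]] <- k
    S2[states[k, 2], states[k, 1]] <- k
  }
  ## gamete transmission: parental haplotypes at (1-c)/2, within-pair
  ## recombinants at c/2 (coinciding outcomes accumulate, so single
  ## heterozygotes segregate 1/2 : 1/2 for every c)
  Tm <- matrix(0, n_hap, n_state)
  for (k in seq_len(n_state)) {
    a <- states[k, 1]
    b <- states[k, 2]
    if (selection) {
      rec1 <- 2L * hap[a, "neutral"] + hap[b, "selected"] + 1L
      rec2 <- 2L * hap[b, "neutral"] + hap[a, "selected"] + 1L
      Tm[a, k] <- Tm[a, k] + (1 - recomb) / 2
      Tm[b, k] <- Tm[b, k] + (1 - recomb) / 2
      Tm[rec1, k] <- Tm[rec1, k] + recomb / 2
      Tm[rec2, k] <- Tm[rec2, k] + recomb / 2
    } else {
      Tm[a, k] <- Tm[a, k] + 1 / 2
      Tm[b, k] <- Tm[b, k] + 1 / 2
    }
  }
  neu_count <- hap[states[, 1], "neutral"] + hap[states[, 2], "neutral"]
  if (selection) {
    sel_count <- hap[states[, 1], "selected"] + hap[states[, 2], "selected"]
    ## locality 1 favors selected allele 1: each copy adds +delta, each
    ## allele-0 copy subtracts delta, so a state contributes
    ## delta * 2 * (copies of allele 1 - 1); locality 2 is the mirror image
    kfac <- 2L * (sel_count - 1L)
  } else {
    sel_count <- rep(0L, n_state)
    kfac <- rep(0L, n_state)
  }
  structure(
    list(
      selection = selection, recomb = recomb,
      hap = hap, n_hap = n_hap,
      states = states, n_state = n_state,
      S2 = S2, Tm = Tm,
      neu_count = as.integer(neu_count),
      sel_count = as.integer(sel_count),
      kfac = as.integer(kfac)
    ),
    class = "pair_basis"
  )
}

#' Table of single-pair diplotype states
#'
#' Human-readable enumeration of the pair-diplotype states used to index
#' genotypes: 10 states when pairs carry a selected locus (4 homozygous
#' and 6 unordered heterozygous combinations, cis and trans double
#' heterozygotes distinct), 3 states for a plain neutral locus.
#'
#' @inheritParams pair_basis
#' @return A data frame with one row per state and the allele content of
#'   its two haplotypes.
#' @export
#' @examples
#' pair_states()          # 10 states
#' pair_states(FALSE)     # 3 states for a lone neutral locus
pair_states <- function(selection = TRUE) {
  b <- pair_basis(selection, recomb = 0)
  out <- data.frame(
    state = seq_len(b$n_state),
    h1_neutral = b$hap[b$states[, 1], "neutral"],
    h2_neutral = b$hap[b$states[, 2], "neutral"]
  )
  if (selection) {
    out$h1_selected <- b$hap[b$states[, 1], "selected"]
    out$h2_selected <- b$hap[b$states[, 2], "selected"]
    out <- out[, c("state", "h1_neutral", "h1_selected",
                   "h2_neutral", "h2_selected")]
  }
  out
}

#' Find the diplotype state index of a pair of haplotypes
#'
#' @param h1,h2 Haplotypes, each a vector `c(neutral, selected)` of 0/1
#'   alleles (or a single 0/1 neutral allele when `selection = FALSE`).
#'   Order does not matter; phase within the pair does (cis and trans
#'   double heterozygotes are different states).
#' @inheritParams pair_basis
#' @return The state index into [pair_states()].
#' @export
#' @examples
#' pair_state(c(1, 1), c(0, 0))  # cis double heterozygote
#' pair_state(c(1, 0), c(0, 1))  # trans double heterozygote
pair_state <- function(h1, h2, selection = TRUE) {
  b <- pair_basis(selection, recomb = 0)
  code <- function(h) {
    if (selection) {
      stopifnot(length(h) == 2, all(h %in% 0:1))
      2L * h[1] + h[2] + 1L
    } else {
      stopifnot(length(h) == 1, h %in% 0:1)
      h + 1L
    }
  }
  b$S2[code(h1), code(h2)]
}

## ------------------------------------------------------------------------
## Multi-pair genotype space
##
## A genotype is a length-n vector of pair-state indices; the full space
## is the n-fold product (10^n or 3^n cells).  Genotype linear indices use
## pair 1 as the fastest-varying digit.
## ------------------------------------------------------------------------

#' Build the n-pair genotype state space
#'
#' Precomputes per-genotype summaries used by the simulator: the additive
#' fitness class (sum of per-pair fitness factors), per-pair digit
#' extraction constants, and the sparse aggregation matrix mapping ordered
#' pairs of gametes to offspring genotypes (random union of gametes).
#'
#' @param basis A [pair_basis()] object.
#' @param n_pairs Number of locus pairs.
#' @return A list of class `"genotype_space"`.
#' @keywords internal
genotype_space <- function(basis, n_pairs) {
  P <- basis$n_state
  H <- basis$n_hap
  n_geno <- P^n_pairs
  n_hapn <- H^n_pairs
  if (n_geno > 2^31) stop("genotype space too large")
  idx0 <- 0:(n_geno - 1)
  kclass <- integer(n_geno)
  for (j in seq_len(n_pairs)) {
    d <- (idx0 %/% P^(j - 1)) %% P
    kclass <- kclass + basis$kfac[d + 1L]
  }
  ## aggregation map of ordered gamete pairs (i1 fastest) into offspring
  ## genotypes: per pair, the offspring diplotype state is S2[h1, h2]
  ut <- sequence(1:n_hapn)           # i1 (1-based) for i1 <= i2,
  i1 <- ut - 1L                      # column-major upper triangle
  i2 <- rep(0:(n_hapn - 1), 1:n_hapn)
  g <- integer(length(i1))
  for (j in seq_len(n_pairs)) {
    d1 <- (i1 %/% H^(j - 1)) %% H
    d2 <- (i2 %/% H^(j - 1)) %% H
    s <- basis$S2[cbind(d1 + 1L, d2 + 1L)]
    g <- g + (s - 1L) * P^(j - 1)
  }
  structure(
    list(basis = basis, n_pairs = n_pairs, P = P, H = H,
         n_geno = n_geno, n_hap = n_hapn, kclass = kclass,
         gmap = as.integer(g)),
    class = "genotype_space"
  )
}

## digit (pair-state, 0-based) of genotype linear indices for pair j
pair_digit <- function(idx0, j, P) (idx0 %/% P^(j - 1)) %% P

## encode a matrix of pair states (rows = genotypes, cols = pairs, values
## 1..P) into 1-based linear genotype indices
encode_genotypes <- function(states, P) {
  states <- rbind(states)
  n_pairs <- ncol(states)
  idx <- rep(0, nrow(states))
  for (j in seq_len(n_pairs)) idx <- idx + (states[, j] - 1) * P^(j - 1)
  as.integer(idx + 1)
}

## marginal distribution of pair j from a genotype-space weight vector
pair_marginal <- function(w, space, j) {
  P <- space$P
  A <- P^(j - 1)
  B <- P^(space$n_pairs - j)
  m <- if (A > 1) colSums(matrix(w, A, P * B)) else w
  if (B > 1) rowSums(matrix(m, P, B)) else as.numeric(m)
}

## gamete pool (probabilities over the n-pair haplotype space) generated
## by a genotype-space weight vector: sequential mode-products with the
## per-pair transmission matrix, pair j transformed in place
pool_from_weights <- function(w, space) {
  tot <- sum(w)
  if (tot <= 0) stop("empty gamete pool: no individuals with positive weight")
  v <- pool_chain_cpp(as.numeric(w), space$basis$Tm, space$P,
                      space$n_pairs)
  v / tot
}

## offspring genotype probabilities under panmictic random union of two
## gametes drawn independently from the pool
offspring_probs <- function(pool, space) {
  q <- egg_probs_cpp(pool, space$gmap, space$n_geno)
  q / sum(q)
}

## haplotype allele table for the full n-pair haplotype space: matrix
## (n_hap^n) x n_pairs of 0-based haplotype codes, pair 1 fastest
hap_codes <- function(space) {
  H <- space$H
  n <- space$n_pairs
  idx0 <- 0:(space$n_hap - 1)
  codes <- matrix(0L, space$n_hap, n)
  for (j in seq_len(n)) codes[, j] <- (idx0 %/% H^(j - 1)) %% H
  codes
}

hap_labels <- function(space) {
  b <- space$basis
  codes <- hap_codes(space)
  lab1 <- if (b$selection) {
    paste0(b$hap[, "neutral"], b$hap[, "selected"])
  } else {
    as.character(b$hap[, "neutral"])
  }
  apply(codes, 1, function(d) paste(lab1[d + 1L], collapse = "|"))
}

## ------------------------------------------------------------------------
## Public operations on explicit genotypes
## ------------------------------------------------------------------------

#' Growth-rate deviation of a genotype in a locality
#'
#' Loci under selection act additively on the clonal growth rate: in
#' locality 1 each copy of selected allele 1 adds `delta` (days^-1) and
#' each copy of allele 0 subtracts `delta`; locality 2 reverses the signs.
#' The genotype's intrinsic growth rate is `r + theta(g, l)`, which
#' therefore varies between `r - 2*s*delta` and `r + 2*s*delta` over the
#' `s` selected loci.
#'
#' @param genotype Integer vector of pair-state indices (see
#'   [pair_states()]), one entry per locus pair.
#' @param locality Locality index, 1 or 2.
#' @param delta Additive fitness component per allele copy (days^-1).
#' @param selection Logical; `FALSE` means no selected loci (theta is 0).
#' @return The growth-rate deviation in days^-1.
#' @export
#' @examples
#' ## homozygous for the locality-1-favored allele at all 5 selected loci
#' g <- rep(pair_state(c(0, 1), c(0, 1)), 5)
#' theta(g, 1, delta = 1e-2)  # +0.1 = +2 * 5 * delta
theta <- function(genotype, locality, delta, selection = TRUE) {
  if (!locality %in% c(1, 2)) stop("locality must be 1 or 2")
  if (!selection || delta == 0) return(0)
  b <- pair_basis(TRUE, recomb = 0)
  stopifnot(all(genotype %in% seq_len(b$n_state)))
  sgn <- if (locality == 1) 1 else -1
  sgn * delta * sum(b$kfac[genotype])
}

#' Gamete distribution of a genotype
#'
#' Probability distribution over gamete haplotypes produced by one
#' genotype.  Within a locus pair, parental haplotypes are transmitted
#' with probability `(1 - recomb)/2` each and within-pair recombinants
#' with `recomb/2` each; distinct pairs assort independently (free
#' recombination between pairs).
#'
#' @inheritParams theta
#' @param recomb Within-pair recombination fraction, in `[0, 0.5]`.
#' @return Named numeric vector of probabilities over the full haplotype
#'   space (names give the per-pair `neutral,selected` alleles separated
#'   by `|`), summing to 1, with attribute `hap_codes`.
#' @export
#' @examples
#' ## single cis double heterozygote, c = 0.1
#' gamete_distribution(pair_state(c(1, 1), c(0, 0)), recomb = 0.1)
gamete_distribution <- function(genotype, recomb, selection = TRUE) {
  b <- pair_basis(selection, recomb)
  space <- genotype_space(b, length(genotype))
  w <- numeric(space$n_geno)
  w[encode_genotypes(matrix(genotype, nrow = 1), space$P)] <- 1
  p <- pool_from_weights(w, space)
  names(p) <- hap_labels(space)
  attr(p, "hap_codes") <- hap_codes(space)
  p
}

#' Gamete pool of a weighted set of genotypes
#'
#' Sexual reproduction is panmictic: the population gamete pool is the
#' weight-averaged mixture of the per-genotype gamete distributions.
#'
#' @param genotypes Matrix of pair-state indices, one row per genotype,
#'   one column per locus pair (a vector is taken as a single genotype).
#' @param weights Non-negative weights (relative contributions of the
#'   genotypes to the pool, e.g. end-of-season densities); at least one
#'   must be positive.
#' @inheritParams gamete_distribution
#' @return Named probability vector over haplotypes, as
#'   [gamete_distribution()].
#' @export
#' @examples
#' ## 3 AA : 1 Aa at one neutral locus -> allele A at 7/8
#' gamete_pool(rbind(1, 2), c(3, 1), recomb = 0, selection = FALSE)
gamete_pool <- function(genotypes, weights, recomb, selection = TRUE) {
  genotypes <- rbind(genotypes)
  stopifnot(nrow(genotypes) == length(weights), all(weights >= 0))
  if (sum(weights) <= 0) {
    stop("empty gamete pool: all genotype weights are zero")
  }
  b <- pair_basis(selection, recomb)
  space <- genotype_space(b, ncol(genotypes))
  w <- numeric(space$n_geno)
  idx <- encode_genotypes(genotypes, space$P)
  for (i in seq_along(idx)) w[idx[i]] <- w[idx[i]] + weights[i]
  p <- pool_from_weights(w, space)
  names(p) <- hap_labels(space)
  attr(p, "hap_codes") <- hap_codes(space)
  p
}
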