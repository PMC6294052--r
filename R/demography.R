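## ------------------------------------------------------------------------
## Within-generation demography: deterministic logistic clonal growth with
## a shared carrying capacity, stochastic diapausing-egg production by
## random union of gametes, egg-bank survival and hatching (deterministic
## fractions above a 1,000-egg census, binomial sampling below), and
## multinomial egg migration.
## ------------------------------------------------------------------------

#' Deterministic logistic clonal growth of competing genotypes
#'
#' Integrates the coupled logistic system
#' `dN_g/dt = N_g * r_g * (1 - sum(N)/K)` from `t = 0` to `t = tau`.  The
#' carrying capacity is shared and genotype-independent, so each density
#' satisfies `N_g(t) = N_g(0) * exp(r_g * Psi(t))` where the crowding
#' integral `Psi(t) = integral of (1 - sum(N)/K)` obeys a single scalar
#' ODE; the implementation solves that reduced form (closed form when all
#' growth rates coincide, adaptive stiff integration otherwise).
#'
#' @param n0 Non-negative initial densities, one per genotype.
#' @param r Intrinsic growth rates (days^-1), scalar or one per genotype.
#'   Non-positive rates are allowed (such genotypes decay while the
#'   population is below `K`).
#' @param K Shared carrying capacity (individuals), `> 0`.
#' @param tau Length of the growth season (days).
#' @param rtol Relative tolerance of the integration.
#' @return Densities at `t = tau`; genotypes starting at zero stay zero.
#' @export
#' @examples
#' asexual_growth(1, r = 0.3, K = 2e7, tau = 60)  # ~1.53e7
asexual_growth <- function(n0, r, K, tau, rtol = 1e-8) {
  stopifnot(all(n0 >= 0), K > 0, tau >= 0)
  S0 <- sum(n0)
  if (S0 == 0 || tau == 0) return(n0)
  r <- rep_len(r, length(n0))
  pos <- n0 > 0
  rpos <- sort(unique(r[pos]))
  if (length(rpos) == 1L) {
    ## single growth-rate class: textbook logistic for the total, all
    ## genotypes scale by the same factor
    Stau <- K / (1 + (K / S0 - 1) * exp(-rpos * tau))
    out <- n0 * (Stau / S0)
  } else {
    A <- as.numeric(rowsum(n0[pos], match(r[pos], rpos)))
    Psi <- crowding_integral_cpp(A, rpos, K, tau, rtol)
    out <- n0 * exp(r * Psi)
  }
  if (any(!is.finite(out))) stop("numerical failure in logistic integration")
  out
}

## rate applied to an egg pool: deterministic fraction at or above the
## census threshold, per-genotype binomial draws (on rounded counts) below
apply_egg_rate <- function(counts, rate, threshold = 1000) {
  tot <- sum(counts)
  if (tot == 0) return(counts)
  if (tot < threshold) {
    b <- round(counts)
    as.numeric(rbinom(length(b), b, rate))
  } else {
    counts * rate
  }
}

## hatching keeps the complement so that the unhatched remainder is exact
## in both regimes
hatch_split <- function(bank, lambda, threshold = 1000) {
  tot <- sum(bank)
  if (tot > 0 && tot < threshold) {
    b <- round(bank)
    h <- as.numeric(rbinom(length(b), b, lambda))
    list(hatched = h, remaining = as.numeric(b) - h)
  } else {
    list(hatched = bank * lambda, remaining = bank * (1 - lambda))
  }
}

#' Diapausing-egg production by panmictic sexual reproduction
#'
#' At the end of the growth season a fraction `m` of females becomes
#' sexual, a fraction `sr` of their offspring are female and each sexual
#' female leaves `e` diapausing eggs, so the cohort totals
#' `round(sum(N(tau)) * m * sr * e)` eggs.  The genotype composition is
#' always sampled: each egg is the random union of two gametes drawn from
#' the population gamete pool, regardless of how many individuals are
#' involved.
#'
#' @param densities End-of-season plankton densities over the genotype
#'   space of `model`.
#' @param model A [sim_model()] object.
#' @return Integer-valued egg counts over the genotype space (an all-zero
#'   cohort if the plankton is extinct).
#' @export
produce_eggs <- function(densities, model) {
  p <- model$params
  total <- round(sum(densities) * p$m * p$sr * p$e)
  if (total >= 2^31) stop("egg cohort too large for multinomial sampling")
  if (sum(densities) <= 0 || total < 1) return(numeric(model$space$n_geno))
  pool <- pool_from_weights(densities, model$space)
  q <- offspring_probs(pool, model$space)
  as.numeric(rmultinom(1, total, q))
}

#' One year of diapausing-egg bank dynamics
#'
#' The newly produced cohort joins the sediment bank; every egg then
#' survives the year with probability `gamma` (age-independent when a
#' bank is modeled), and a fraction `lambda` of the survivors hatches at
#' the start of the next growing season.  Above a total of 1,000 eggs
#' the fractions are applied deterministically to real-valued counts;
#' below it survival and hatching are per-genotype binomial draws on
#' integer counts.
#'
#' @param bank Egg counts carried over in the sediment (zero vector for
#'   the first year or when no bank is modeled).
#' @param cohort Newly produced egg counts (same length).
#' @param params A [sim_params()] object (uses `gamma`, `lambda`,
#'   `egg_threshold`).
#' @return A list with `hatched` (recruits to the plankton) and `bank`
#'   (unhatched surviving eggs; discard it when no bank is modeled).
#' @export
#' @examples
#' p <- sim_params()
#' bank_update(10000, 0, p)  # hatched 351, retained bank 7279 (approx.)
bank_update <- function(bank, cohort, params) {
  stopifnot(all(bank >= 0), all(cohort >= 0))
  surv <- apply_egg_rate(bank + cohort, params$gamma, params$egg_threshold)
  h <- hatch_split(surv, params$lambda, params$egg_threshold)
  list(hatched = h$hatched, bank = h$remaining)
}

#' Draw migrant diapausing eggs from a donor egg bank
#'
#' `n_migrants` eggs are drawn multinomially from the donor bank's
#' genotype distribution.  Migration is assumed to have a negligible
#' effect on the donor, whose bank is not depleted.
#'
#' @param donor_bank Egg counts of the donor bank.
#' @param n_migrants Number of migrant eggs per sexual generation.
#' @return Migrant egg counts (all zero if the donor bank is empty).
#' @export
migrate <- function(donor_bank, n_migrants) {
  stopifnot(n_migrants >= 0, all(donor_bank >= 0))
  tot <- sum(donor_bank)
  if (n_migrants == 0 || tot == 0) return(numeric(length(donor_bank)))
  as.numeric(rmultinom(1, n_migrants, donor_bank / tot))
}
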