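## ------------------------------------------------------------------------
## Scenario orchestration: parameter sets, the source population, the
## founding event, the yearly generation loop over both localities, and
## replicate / experiment management with reproducible seeding.
## ------------------------------------------------------------------------

#' Simulation parameters
#'
#' Collects all model parameters with defaults matching field-calibrated
#' values for rotifer and cladoceran populations: annual egg-bank survival
#' `gamma = 0.763` and hatching fraction `lambda = 0.046` (estimated from
#' rotifer diapausing-egg banks), a 60-day growth season, sexual
#' proportion 0.7, sex ratio 0.5 and 3 diapausing eggs per sexual female.
#'
#' @param founders Number of founding diapausing eggs per locality (F).
#' @param migrants Migrant diapausing eggs exchanged per sexual
#'   generation (M).
#' @param gamma Annual survival proportion of eggs in the sediment.
#' @param lambda Annual hatching proportion of diapausing eggs.
#' @param generations Number of sexual generations to simulate (Y).
#' @param tau Length of the asexual growth season (days).
#' @param r Basal clonal growth rate (days^-1).
#' @param K Shared carrying capacity (individuals).
#' @param m Sexual proportion (fraction of females becoming sexual).
#' @param sr Sex ratio (fraction of sexual offspring that are female).
#' @param e Diapausing eggs produced per sexual female.
#' @param n_loci Number of neutral marker loci (n).
#' @param s_loci Number of selected loci (s); either 0 (neutral scenario)
#'   or equal to `n_loci` (each neutral locus linked to one selected
#'   locus).
#' @param delta Additive fitness component per selected-allele copy
#'   (days^-1); locality 1 favors allele 1, locality 2 allele 0.
#' @param recomb Within-pair recombination fraction between a neutral
#'   locus and its selected partner, in `[0, 0.5]`.
#' @param bank Logical; model a persistent, age-independent diapausing
#'   egg bank (`TRUE`) or let only the latest cohort survive to its first
#'   hatching season (`FALSE`)?
#' @param replicates Default number of replicate simulations.
#' @param egg_threshold Egg census below which survival and hatching are
#'   sampled binomially instead of applied as deterministic fractions.
#' @return A validated list of class `"sim_params"`.
#' @export
#' @examples
#' sim_params(K = 2e4, migrants = 100)
sim_params <- function(founders = 1, migrants = 2, gamma = 0.763,
                       lambda = 0.046, generations = 1000, tau = 60,
                       r = 0.3, K = 2e7, m = 0.7, sr = 0.5, e = 3,
                       n_loci = 5, s_loci = 0, delta = 0, recomb = 0.5,
                       bank = TRUE, replicates = 10,
                       egg_threshold = 1000) {
  p <- list(founders = founders, migrants = migrants, gamma = gamma,
            lambda = lambda, generations = generations, tau = tau, r = r,
            K = K, m = m, sr = sr, e = e, n_loci = as.integer(n_loci),
            s_loci = as.integer(s_loci), delta = delta, recomb = recomb,
            bank = isTRUE(bank), replicates = as.integer(replicates),
            egg_threshold = egg_threshold)
  bad <- character(0)
  chk <- function(ok, key) if (!ok) bad <<- c(bad, key)
  chk(founders >= 1, "founders (F >= 1)")
  chk(migrants >= 0, "migrants (M >= 0)")
  chk(gamma >= 0 && gamma <= 1, "gamma (in [0, 1])")
  chk(lambda >= 0 && lambda <= 1, "lambda (in [0, 1])")
  chk(generations >= 1, "generations (y >= 1)")
  chk(tau > 0, "tau (> 0)")
  chk(K > 0, "K (> 0)")
  chk(m >= 0 && m <= 1, "m (in [0, 1])")
  chk(sr >= 0 && sr <= 1, "sr (in [0, 1])")
  chk(e >= 0, "e (>= 0)")
  chk(p$n_loci >= 1, "n (>= 1)")
  chk(p$s_loci == 0 || p$s_loci == p$n_loci, "s (0 or equal to n)")
  chk(delta >= 0, "delta (>= 0)")
  chk(recomb >= 0 && recomb <= 0.5, "c (in [0, 0.5])")
  chk(replicates >= 1, "replicates (>= 1)")
  if (length(bad)) {
    stop("invalid parameter value(s): ", paste(bad, collapse = ", "))
  }
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Colonization simulation parameters\n")
  cat(sprintf("  F = %g founders, M = %g migrants/generation, K = %g, r = %g /d\n",
              x$founders, x$migrants, x$K, x$r))
  cat(sprintf("  season tau = %g d, m = %g, sr = %g, e = %g\n",
              x$tau, x$m, x$sr, x$e))
  cat(sprintf("  egg bank: %s (gamma = %g, lambda = %g)\n",
              if (x$bank) "present" else "absent", x$gamma, x$lambda))
  cat(sprintf("  loci: n = %d neutral, s = %d selected (delta = %g, c = %g)\n",
              x$n_loci, x$s_loci, x$delta, x$recomb))
  cat(sprintf("  %d sexual generations, %d replicates\n",
              x$generations, x$replicates))
  invisible(x)
}

#' Precomputed simulation model
#'
#' Binds a parameter set to its genetic state space: the single-pair
#' basis, the n-pair genotype space and the per-genotype growth rates in
#' each locality.  Building the space is moderately expensive for
#' selection scenarios (10^n genotypes), so a model is constructed once
#' and shared across replicates.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `"sim_model"` with elements `params`, `basis`,
#'   `space`, and growth-rate vectors `r1`, `r2` (days^-1).
#' @export
sim_model <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  selection <- params$s_loci > 0
  basis <- pair_basis(selection, params$recomb)
  space <- genotype_space(basis, params$n_loci)
  if (selection && params$delta > 0) {
    r1 <- params$r + params$delta * space$kclass
    r2 <- params$r - params$delta * space$kclass
    ## fitness classes: distinct values of the additive deviation, with a
    ## per-genotype class index for fast growth updates
    kvals <- sort(unique(space$kclass))
    kidx <- match(space$kclass, kvals)
    rv1 <- params$r + params$delta * kvals
    rv2 <- params$r - params$delta * kvals
  } else {
    r1 <- r2 <- params$r
    kvals <- kidx <- rv1 <- rv2 <- NULL
  }
  structure(list(params = params, basis = basis, space = space,
                 r1 = r1, r2 = r2, kidx = kidx, rv1 = rv1, rv2 = rv2),
            class = "sim_model")
}

## growth of a genotype-space density vector in locality `l`, using the
## model's precomputed fitness classes (same reduced-form integration as
## asexual_growth)
grow_by_class <- function(n0, model, l) {
  p <- model$params
  S0 <- sum(n0)
  if (S0 == 0) return(n0)
  if (is.null(model$kidx)) {
    Stau <- p$K / (1 + (p$K / S0 - 1) * exp(-p$r * p$tau))
    return(n0 * (Stau / S0))
  }
  rv <- if (l == 1) model$rv1 else model$rv2
  A <- as.numeric(rowsum(n0, model$kidx))
  Psi <- crowding_integral_cpp(A, rv, p$K, p$tau, 1e-8)
  out <- n0 * exp(rv * Psi)[model$kidx]
  if (any(!is.finite(out))) stop("numerical failure in logistic integration")
  out
}

#' Draw a source population
#'
#' The source is an infinite population in Hardy-Weinberg and linkage
#' equilibrium; all loci (neutral and selected alike) are neutral in the
#' source, so founders carry no preadaptation.  Allele frequencies are
#' drawn uniformly on (0, 1), independently per locus and per replicate,
#' unless supplied.
#'
#' @param params A [sim_params()] object.
#' @param p_neutral,p_selected Optional fixed allele-1 frequencies
#'   (recycled to `n_loci` / `s_loci`).
#' @return List of class `"source_population"` with `p_neutral` and
#'   `p_selected`.
#' @export
source_population <- function(params, p_neutral = NULL, p_selected = NULL) {
  p_neutral <- if (is.null(p_neutral)) runif(params$n_loci) else
    rep_len(p_neutral, params$n_loci)
  p_selected <- if (params$s_loci == 0) numeric(0) else
    if (is.null(p_selected)) runif(params$s_loci) else
      rep_len(p_selected, params$s_loci)
  stopifnot(all(p_neutral >= 0 & p_neutral <= 1),
            all(p_selected >= 0 & p_selected <= 1))
  structure(list(p_neutral = p_neutral, p_selected = p_selected),
            class = "source_population")
}

## draw `n_ind` diploid genotypes from the source (HWE, linkage
## equilibrium: two independent haplotypes, loci independent) and tally
## them on the genotype space
draw_source_genotypes <- function(source, n_ind, model) {
  space <- model$space
  b <- space$basis
  n <- space$n_pairs
  hapdraw <- function() {
    nu <- matrix(rbinom(n_ind * n, 1, rep(source$p_neutral, each = n_ind)),
                 n_ind, n)
    if (b$selection) {
      sg <- matrix(rbinom(n_ind * n, 1, rep(source$p_selected, each = n_ind)),
                   n_ind, n)
      2L * nu + sg
    } else {
      nu
    }
  }
  a1 <- hapdraw()
  a2 <- hapdraw()
  states <- matrix(b$S2[cbind(as.vector(a1) + 1L, as.vector(a2) + 1L)],
                   n_ind, n)
  idx <- encode_genotypes(states, space$P)
  as.numeric(tabulate(idx, nbins = space$n_geno))
}

#' Found the two local populations
#'
#' Each locality receives `founders` diapausing eggs drawn independently
#' from the same source population.  Founding eggs hatch immediately and
#' fully (establishment is taken as given: a single diapausing egg
#' suffices to start a clonal population), entering the plankton at
#' `y = t = 0`.
#'
#' @param source A [source_population()] object.
#' @param founders Number of founding eggs per locality.
#' @param model A [sim_model()] object.
#' @return List of two genotype-space tally vectors (localities 1 and 2).
#' @export
found_populations <- function(source, founders, model) {
  stopifnot(founders >= 1)
  list(draw_source_genotypes(source, founders, model),
       draw_source_genotypes(source, founders, model))
}

## end-of-year demography shared by the founding season and ordinary
## generations: grow the plankton to tau, produce eggs, apply bank
## survival, then draw migrants reciprocally from the post-survival
## (pre-exchange) banks.  Migrants are immigrant individuals: they
## recruit fully into the other locality's next hatchling cohort, while
## the donor bank is not depleted.  `carry` holds unhatched sediment eggs
## (zero vectors when no bank is modeled).
season_and_exchange <- function(plankton, carry, model) {
  p <- model$params
  ntau <- vector("list", 2)
  banks <- vector("list", 2)
  for (l in 1:2) {
    grown <- grow_by_class(plankton[[l]], model, l)
    cohort <- produce_eggs(grown, model)
    banks[[l]] <- apply_egg_rate(carry[[l]] + cohort, p$gamma,
                                 p$egg_threshold)
    ntau[[l]] <- sum(grown)
  }
  arrivals <- list(migrate(banks[[2]], p$migrants),
                   migrate(banks[[1]], p$migrants))
  list(banks = banks, arrivals = arrivals,
       n_tau = c(ntau[[1]], ntau[[2]]))
}

#' Advance the coupled two-locality system by one sexual generation
#'
#' Executes one full yearly cycle: hatching of the sediment eggs and
#' recruitment of the immigrant individuals that arrived over winter,
#' recording of FST/FSTQ on that recruit pool, logistic clonal growth to
#' `tau`, diapausing-egg production, egg-bank survival, and the
#' reciprocal draw of next year's migrants from the pre-exchange banks.
#' Both localities are updated synchronously.  Because the founding
#' season already ends with a migrant draw, the first recorded
#' generation reflects migration, not the bare foundation.
#'
#' @param state List with `banks` (two genotype-space egg-bank vectors)
#'   and `arrivals` (two vectors of immigrant individuals awaiting
#'   recruitment), as returned by this function or by the founding
#'   season inside [run_replicate()].
#' @param model A [sim_model()] object.
#' @return List with the updated `state`, a one-row `record` (list with
#'   `fst`, `fstq`, `h_t`, `h_s`, `census_1`, `census_2`, `n_tau_1`,
#'   `n_tau_2`) and `extinct` (TRUE when a locality has neither plankton
#'   nor eggs nor inbound migrants).
#' @export
run_generation <- function(state, model) {
  p <- model$params
  plankton <- vector("list", 2)
  carry <- vector("list", 2)
  for (l in 1:2) {
    h <- hatch_split(state$banks[[l]], p$lambda, p$egg_threshold)
    plankton[[l]] <- h$hatched + state$arrivals[[l]]
    ## without a bank, eggs that fail to hatch in their first season are
    ## senescent (survival zero at age > 1) and are discarded
    carry[[l]] <- if (p$bank) h$remaining else numeric(model$space$n_geno)
  }
  stat <- fst_from_states(plankton[[1]], plankton[[2]], model)
  se <- season_and_exchange(plankton, carry, model)
  extinct <- any(vapply(1:2, function(l) {
    sum(plankton[[l]]) == 0 && sum(se$banks[[l]]) == 0 &&
      sum(se$arrivals[[l]]) == 0
  }, logical(1)))
  record <- list(fst = stat$fst, fstq = stat$fstq, h_t = stat$h_t,
                 h_s = stat$h_s, census_1 = stat$census_1,
                 census_2 = stat$census_2, n_tau_1 = se$n_tau[1],
                 n_tau_2 = se$n_tau[2])
  list(state = list(banks = se$banks, arrivals = se$arrivals),
       record = record, extinct = extinct)
}

#' Run one replicate simulation
#'
#' Draws a fresh source population, founds both localities, runs the
#' founding season (growth, egg production, survival and the first
#' migrant exchange) and then `generations` full yearly cycles, recording
#' FST and FSTQ just after hatching each year.  The whole trajectory is
#' deterministic given `seed`.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed for this replicate.
#' @param model Optional prebuilt [sim_model()] (rebuilt from `params`
#'   when `NULL`); passing one avoids rebuilding the genotype space.
#' @param record_every Record every `record_every`-th generation
#'   (generations 1 and Y are always recorded).
#' @return Object of class `"replicate_result"`: a list with `records`
#'   (tibble of per-generation summaries), `init_fst` (FST just after
#'   foundation, before any migration), `extinct`, `extinct_at`, `seed`
#'   and `params`.
#' @export
#' @examples
#' r <- run_replicate(sim_params(K = 2e4, generations = 5), seed = 1)
#' r$records
run_replicate <- function(params, seed, model = NULL,
                          record_every = 1L) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  model <- model %||% sim_model(params)
  src <- source_population(params)
  founders <- found_populations(src, params$founders, model)
  init <- fst_from_states(founders[[1]], founders[[2]], model)
  zero <- numeric(model$space$n_geno)
  se0 <- season_and_exchange(founders, list(zero, zero), model)
  state <- list(banks = se0$banks, arrivals = se0$arrivals)
  Y <- params$generations
  keep <- unique(c(1L, seq(1L, Y, by = record_every), Y))
  rec <- matrix(NA_real_, length(keep), 9,
                dimnames = list(NULL, c("y", "fst", "fstq", "h_t", "h_s",
                                        "census_1", "census_2", "n_tau_1",
                                        "n_tau_2")))
  extinct <- FALSE
  extinct_at <- NA_integer_
  ri <- 0L
  for (y in seq_len(Y)) {
    gen <- run_generation(state, model)
    state <- gen$state
    if (y %in% keep) {
      ri <- ri + 1L
      rec[ri, ] <- c(y, unlist(gen$record))
    }
    if (gen$extinct) {
      extinct <- TRUE
      extinct_at <- y
      break
    }
  }
  records <- tibble::as_tibble(as.data.frame(rec[seq_len(ri), ,
                                                 drop = FALSE]))
  structure(list(records = records, init_fst = init$fst,
                 extinct = extinct, extinct_at = extinct_at, seed = seed,
                 params = params),
            class = "replicate_result")
}

#' @export
print.replicate_result <- function(x, ...) {
  cat(sprintf("Replicate (seed %d): %d recorded generations%s\n",
              x$seed, nrow(x$records),
              if (x$extinct) sprintf(", EXTINCT at y = %d", x$extinct_at)
              else ""))
  cat(sprintf("  FST after foundation %.4f; final FST %.4f\n", x$init_fst,
              x$records$fst[nrow(x$records)]))
  invisible(x)
}

## map between Table-style parameter symbols (used in configs, grids and
## CSV columns) and sim_params argument names
symbol_map <- c(F = "founders", M = "migrants", gamma = "gamma",
                lambda = "lambda", y = "generations", tau = "tau",
                r = "r", K = "K", m = "m", sr = "sr", e = "e",
                n = "n_loci", s = "s_loci", delta = "delta",
                c = "recomb", bank = "bank", replicates = "replicates")

params_with <- function(base, symbols) {
  stopifnot(inherits(base, "sim_params"))
  args <- unclass(base)
  args$egg_threshold <- NULL
  over <- setNames(as.list(symbols), symbol_map[names(symbols)])
  do.call(sim_params, modifyList(args, over))
}

#' Run a replicated parameter-grid experiment
#'
#' Crosses a grid of parameter combinations with independent replicates,
#' spawning one reproducible seed per (combination, replicate) from the
#' master seed, and returns one tidy row per recorded generation.
#'
#' @param grid Data frame of parameter overrides, one row per
#'   combination, columns named by parameter symbol (`F`, `M`, `gamma`,
#'   `lambda`, `y`, `tau`, `r`, `K`, `m`, `sr`, `e`, `n`, `s`, `delta`,
#'   `c`, `bank`).  `NULL` runs the base parameters alone.
#' @param params Base [sim_params()] the grid overrides.
#' @param replicates Replicates per combination (defaults to
#'   `params$replicates`).
#' @param seed Master seed.
#' @param record_every Generation-recording stride passed to
#'   [run_replicate()].
#' @param label Experiment label written to the `preset` column.
#' @param verbose Emit per-replicate progress messages (seed, extinction
#'   events)?
#' @return A tibble with columns `preset, replicate, seed, y, K, r, M, F,
#'   delta, c, bank, fst, fstq, h_t, h_s, census_1, census_2,
#'   extinct_flag` plus `init_fst` and end-of-season densities
#'   `n_tau_1`, `n_tau_2`.
#' @export
#' @examples
#' run_experiment(data.frame(K = c(2e3, 2e4)),
#'                params = sim_params(generations = 3), replicates = 2,
#'                seed = 1)
run_experiment <- function(grid = NULL, params = sim_params(),
                           replicates = NULL, seed = 1,
                           record_every = 1L, label = "custom",
                           verbose = FALSE) {
  if (is.null(grid)) grid <- data.frame(row.names = 1)
  stopifnot(nrow(grid) >= 1)
  unknown <- setdiff(names(grid), names(symbol_map))
  if (length(unknown)) {
    stop("unknown grid parameter(s): ", paste(unknown, collapse = ", "))
  }
  replicates <- replicates %||% params$replicates
  set.seed(seed)
  seeds <- matrix(sample.int(2147483647L, nrow(grid) * replicates),
                  nrow(grid), replicates)
  out <- vector("list", nrow(grid) * replicates)
  for (i in seq_len(nrow(grid))) {
    pi <- params_with(params, as.list(grid[i, , drop = FALSE]))
    model <- sim_model(pi)
    for (k in seq_len(replicates)) {
      s <- seeds[i, k]
      if (verbose) {
        message(sprintf("[%s] combo %d/%d replicate %d/%d (seed %d)",
                        label, i, nrow(grid), k, replicates, s))
      }
      res <- run_replicate(pi, s, model = model,
                           record_every = record_every)
      if (verbose && res$extinct) {
        message(sprintf("  extinction at generation %d", res$extinct_at))
      }
      rr <- res$records
      out[[(i - 1) * replicates + k]] <- tibble::tibble(
        preset = label, replicate = k, seed = s, y = rr$y,
        K = pi$K, r = pi$r, M = pi$migrants, F = pi$founders,
        delta = pi$delta, c = pi$recomb, bank = pi$bank,
        fst = rr$fst, fstq = rr$fstq, h_t = rr$h_t, h_s = rr$h_s,
        census_1 = rr$census_1, census_2 = rr$census_2,
        extinct_flag = res$extinct, init_fst = res$init_fst,
        n_tau_1 = rr$n_tau_1, n_tau_2 = rr$n_tau_2
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Carrying capacity expressed as a density
#'
#' Converts a carrying capacity in individuals to individuals per litre
#' for a pond of the given surface area and depth (the default 200 m^2 x
#' 1 m pond holds 2e5 L, so `K = 2e7` corresponds to 100 individuals/L).
#'
#' @param K Carrying capacity (individuals).
#' @param area_m2 Pond surface area (m^2).
#' @param depth_m Pond depth (m).
#' @return Density in individuals per litre.
#' @export
#' @examples
#' density_per_litre(2e7)  # 100
density_per_litre <- function(K, area_m2 = 200, depth_m = 1) {
  K / (area_m2 * depth_m * 1000)
}
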