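test_that("parameter validation enforces the documented ranges", {
  expect_error(sim_params(recomb = 0.7), "c \\(in")
  expect_error(sim_params(founders = 0), "F")
  expect_error(sim_params(s_loci = 3, n_loci = 5), "s \\(0 or equal")
  p <- sim_params()
  expect_equal(p$gamma, 0.763)
  expect_equal(p$lambda, 0.046)
  expect_equal(p$tau, 60)
  expect_equal(c(p$m, p$sr, p$e, p$n_loci), c(0.7, 0.5, 3, 5))
})

test_that("founding draws reflect source frequencies", {
  p <- sim_params(n_loci = 3, s_loci = 0, K = 2e3)
  m <- sim_model(p)
  ## frequency-1 source: both localities monomorphic for the same
  ## allele, so differentiation is flagged undefined (H_T = 0)
  src <- source_population(p, p_neutral = 1)
  fp <- found_populations(src, 1, m)
  f <- fst_from_states(fp[[1]], fp[[2]], m)
  expect_true(is.na(f$fst))
  expect_equal(f$h_t, 0)
  ## interior frequencies, F = 1: sampling variance makes mean FST > 0
  set.seed(2)
  src2 <- source_population(p, p_neutral = 0.5)
  fsts <- replicate(300, {
    fp <- found_populations(src2, 1, m)
    fst_from_states(fp[[1]], fp[[2]], m)$fst
  })
  expect_gt(mean(fsts, na.rm = TRUE), 0.1)
  ## many founders: differentiation washes out
  fst50 <- replicate(100, {
    fp <- found_populations(src2, 50, m)
    fst_from_states(fp[[1]], fp[[2]], m)$fst
  })
  expect_lt(mean(fst50, na.rm = TRUE), 0.05)
})

test_that("post-foundation FST decreases in expectation with founder number", {
  p <- sim_params(K = 2e3)
  m <- sim_model(p)
  set.seed(17)
  mean_fst <- function(founders, nrep = 500) {
    mean(replicate(nrep, {
      src <- source_population(p)
      fp <- found_populations(src, founders, m)
      fst_from_states(fp[[1]], fp[[2]], m)$fst
    }), na.rm = TRUE)
  }
  f <- vapply(c(1, 2, 5, 50), mean_fst, numeric(1))
  expect_true(all(diff(f) < 0))
})

test_that("replicates are reproducible and order-independent", {
  p <- sim_params(K = 2e3, generations = 4)
  m <- sim_model(p)
  a <- run_replicate(p, seed = 123, model = m)
  b <- run_replicate(p, seed = 123, model = m)
  expect_identical(a$records, b$records)
  ## a different seed gives a different trajectory
  d <- run_replicate(p, seed = 124, model = m)
  expect_false(identical(a$records$fst, d$records$fst))
  ## one generation -> a single record at y = 1
  p1 <- sim_params(K = 2e3, generations = 1)
  r1 <- run_replicate(p1, seed = 5)
  expect_equal(nrow(r1$records), 1)
  expect_equal(r1$records$y, 1)
})

test_that("identically founded localities without migration stay undiverged
           in the deterministic regime", {
  ## at K = 2e7 egg handling is deterministic and the only asymmetry is
  ## the multinomial draw of ~2e7 eggs, so FST stays at sampling noise
  p <- sim_params(K = 2e7, migrants = 0, generations = 3)
  m <- sim_model(p)
  set.seed(9)
  src <- source_population(p)
  w <- eggbanksim:::draw_source_genotypes(src, 10, m)
  zero <- numeric(m$space$n_geno)
  se <- eggbanksim:::season_and_exchange(list(w, w), list(zero, zero), m)
  state <- list(banks = se$banks, arrivals = se$arrivals)
  for (y in 1:3) {
    gen <- run_generation(state, m)
    state <- gen$state
    expect_lt(gen$record$fst, 1e-4)
  }
})

test_that("a locality with neither plankton nor eggs ends the replicate", {
  ## gamma = 0 destroys every egg, so year 1 finds empty banks
  p <- sim_params(K = 2e3, gamma = 0, generations = 5)
  r <- run_replicate(p, seed = 3)
  expect_true(r$extinct)
  expect_equal(r$extinct_at, 1)
  expect_lt(nrow(r$records), 5)
})

test_that("experiment tables cross grid with replicates reproducibly", {
  grid <- data.frame(K = c(2e3, 2e4))
  p <- sim_params(generations = 2)
  tab <- run_experiment(grid, params = p, replicates = 2, seed = 42)
  expect_equal(nrow(tab), 2 * 2 * 2)  # combos x replicates x generations
  expect_setequal(unique(tab$K), c(2e3, 2e4))
  tab2 <- run_experiment(grid, params = p, replicates = 2, seed = 42)
  expect_identical(tab, tab2)
  ## each row's replicate is reproducible standalone from its seed
  s <- tab$seed[tab$K == 2e4 & tab$replicate == 2][1]
  solo <- run_replicate(params_with <- eggbanksim:::params_with(
    p, list(K = 2e4)), seed = s)
  expect_equal(solo$records$fst,
               tab$fst[tab$K == 2e4 & tab$replicate == 2])
})

test_that("migration erodes differentiation in small populations", {
  ## K = 2e2 with massive migration: FST collapses below its founding
  ## value within a few tens of generations
  p <- sim_params(K = 2e2, migrants = 100, generations = 40)
  m <- sim_model(p)
  finals <- vapply(1:6, function(s) {
    r <- run_replicate(p, seed = s, model = m)
    mean(tail(r$records$fst, 5), na.rm = TRUE) - r$init_fst
  }, numeric(1))
  expect_lt(mean(finals, na.rm = TRUE), 0)
})

test_that("an egg bank slows per-generation FST change", {
  p_bank <- sim_params(K = 2e3, generations = 60, bank = TRUE)
  p_nobank <- sim_params(K = 2e3, generations = 60, bank = FALSE)
  m_b <- sim_model(p_bank)
  m_n <- sim_model(p_nobank)
  step_change <- function(par, mod, s) {
    r <- run_replicate(par, seed = s, model = mod)
    mean(abs(diff(r$records$fst)), na.rm = TRUE)
  }
  ch_b <- mean(vapply(1:6, function(s) step_change(p_bank, m_b, s),
                      numeric(1)))
  ch_n <- mean(vapply(1:6, function(s) step_change(p_nobank, m_n, s),
                      numeric(1)))
  expect_lt(ch_b, ch_n)
})

test_that("carrying capacity converts to the stated pond density", {
  expect_equal(density_per_litre(2e7), 100)
  expect_equal(density_per_litre(2e2), 0.001)
})
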