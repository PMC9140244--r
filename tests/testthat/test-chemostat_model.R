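test_that("Monod kinetics and the fitness conversion behave as stated", {
  expect_equal(monod_growth_rate(0, 0.35, 0.103), 0)
  expect_equal(monod_growth_rate(0.103, 0.35, 0.103), 0.35 / 2)
  expect_equal(monod_growth_rate(0.8, 0.35, 0.103), 0.35 * 0.8 / 0.903)
  expect_error(monod_growth_rate(-0.1, 0.35, 0.103), "non-negative")
  expect_equal(selection_to_malthusian(0, 0.35), 0.35)
  expect_equal(selection_to_malthusian(0.1, 0.35),
               0.35 * (1 + 0.1 * log(2)))
  s <- c(-0.2, 0.001, 0.1, 0.3)
  expect_equal(malthusian_to_selection(selection_to_malthusian(s, 0.35),
                                       0.35), s, tolerance = 1e-12)
})

test_that("steady state solves the Monod fixed point", {
  cp <- chemostat_params()
  ss <- steady_state(cp)
  expect_equal(ss$s_star, 0.12 * 0.103 / 0.23, tolerance = 1e-12)
  # close to (within 10% of) the quoted 2.5e7 cells/mL
  expect_lt(abs(ss$density - 2.5e7) / 2.5e7, 0.1)
  # no consumable substrate means zero density
  cp2 <- chemostat_params(s0 = 0.12 * 0.103 / 0.23 + 1e-12)
  expect_lt(steady_state(cp2)$density, 1)
  expect_error(chemostat_params(dilution_rate = 0.4), "washout")
})

test_that("deterministic ODE integration converges to the analytic fixed point", {
  cp <- chemostat_params()
  out <- chemostat_ode(cp, hours = c(100, 200, 400))
  ss <- steady_state(cp)
  expect_equal(out$s_mm[3], ss$s_star, tolerance = 1e-3)
  expect_equal(out$n_a[3], ss$census, tolerance = 1e-3)
  # already essentially at steady state well before 200 h
  expect_equal(out$n_a[2] / ss$census, 1, tolerance = 0.01)
})

test_that("tau-leap: null event case, determinism and ODE drift", {
  # empty vessel: no events, time advances, substrate stays at S0
  res <- cnvsbi:::chemo_core(0, 0, 0, 0, 0.12, 0.8, 0.103, 32445000, 0.35,
                             20, 0, 0, 0.1, c(0, 5, 10))
  expect_equal(res$n_a, rep(0, 3))
  expect_equal(res$s_mm, rep(0.8, 3))
  # fixed seed gives a bit-identical repeat
  cp <- chemostat_params(volume = 1, inoculum = 1e5)
  ep <- evolution_params(1e-4, 0.1)
  a <- simulate_chemostat(cp, ep, sample_times = c(0, 20, 50), seed = 12)
  b <- simulate_chemostat(cp, ep, sample_times = c(0, 20, 50), seed = 12)
  expect_identical(a$proportion, b$proportion)
  # mean stochastic trajectory tracks the ODE within 2% at large counts
  # once the transient is over (Poisson leaping is first order in the
  # rates, so the mean lags the ODE by a few percent during the
  # exponential growth phase at tau = 0.1 and converges as tau shrinks)
  ep0 <- evolution_params(0, 0, 0, 0)
  hours <- c(60, 100, 150)
  ode <- chemostat_ode(cp, ep0, hours)
  reps <- sapply(1:50, function(r)
    cnvsbi:::chemostat_run(cp, ep0, hours, seed = 5000 + r)$n_a)
  rel <- abs(rowMeans(reps) - ode$n_a) / ode$n_a
  expect_lt(max(rel), 0.02)
  # growth-phase bias shrinks when tau is halved
  reps_fine <- sapply(1:30, function(r)
    cnvsbi:::chemostat_run(cp, ep0, 12, tau = 0.025, seed = 6000 + r)$n_a)
  reps_coarse <- sapply(1:30, function(r)
    cnvsbi:::chemostat_run(cp, ep0, 12, tau = 0.1, seed = 6000 + r)$n_a)
  ode12 <- chemostat_ode(cp, ep0, 12)$n_a
  expect_lt(abs(mean(reps_fine) - ode12) / ode12,
            abs(mean(reps_coarse) - ode12) / ode12)
})

test_that("stochastic census settles near the deterministic steady state", {
  cp <- chemostat_params(volume = 1, inoculum = 1e5)
  ep0 <- evolution_params(0, 0, 0, 0)
  st <- cnvsbi:::chemostat_run(cp, ep0, hours = c(150, 200), seed = 9)
  ss <- steady_state(cp)
  expect_equal(st$n_a[2] / ss$census, 1, tolerance = 0.02)
  expect_equal(st$s_mm[2], ss$s_star, tolerance = 0.05)
  # no mutation: proportions identically zero
  tr <- simulate_chemostat(cp, ep0, sample_times = c(0, 10, 20), seed = 2)
  expect_true(all(tr$proportion == 0))
})

test_that("halving tau leaves mean trajectories essentially unchanged", {
  cp <- chemostat_params(volume = 1, inoculum = 1e5)
  ep <- evolution_params(1e-4, 0.1)
  grid <- seq(0, 200, by = 40)
  mean_traj <- function(tau) {
    rowMeans(sapply(1:30, function(r)
      simulate_chemostat(cp, ep, sample_times = grid, tau = tau,
                         seed = cnvsbi:::child_seed(1234, r))$proportion))
  }
  m1 <- mean_traj(0.1); m2 <- mean_traj(0.05)
  # compare where the proportion is appreciably nonzero
  use <- m1 > 0.05
  expect_lt(max(abs(m1[use] - m2[use]) / m1[use]), 0.1)
})

test_that("both models produce a sigmoidal sweep under strong selection", {
  grid <- default_grid()
  wf <- simulate_wf(evolution_params(1e-5, 0.1), sample_times = grid,
                    seed = 4)
  ch <- simulate_chemostat(eparams = evolution_params(1e-5, 0.1),
                           sample_times = grid, seed = 4)
  for (tr in list(wf, ch)) {
    expect_lt(tr$proportion[1], 0.01)
    expect_gt(max(tr$proportion), 0.9)
    # rises monotonically once established
    est <- tr$proportion > 0.05
    expect_true(all(diff(tr$proportion[est]) > -0.02))
  }
  # the chemostat realizes a weaker per-generation advantage, so its sweep
  # lags the Wright-Fisher sweep; this mismatch is what inference with the
  # wrong model has to absorb
  expect_gt(which(ch$proportion > 0.5)[1], which(wf$proportion > 0.5)[1])
})

test_that("estimate_ne recovers a known Wright-Fisher population size", {
  # at N = 1000 a neutral allele can fix within 1000 generations, where
  # the estimator is undefined; average the first 20 non-absorbed paths
  ests <- c(); r <- 0
  while (length(ests) < 20 && r < 200) {
    r <- r + 1
    p <- wf_neutral_freqs(1000, 0.5, 1000, seed = 8000 + r)
    if (all(p[-(1:100)] > 0 & p[-(1:100)] < 1))
      ests <- c(ests, estimate_ne(p, burn_in_gens = 100))
  }
  expect_length(ests, 20)
  expect_equal(mean(ests), 1000, tolerance = 0.1)
  expect_error(estimate_ne(rep(0.5, 500)), "no drift")
  expect_error(estimate_ne(c(0.5, 0.6), burn_in_gens = 100), "too short")
})
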