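test_that("adaptive distance: identity, scaling and homogeneity", {
  expect_equal(adaptive_distance(c(0.1, 0.2), c(0.1, 0.2)), 0)
  expect_equal(adaptive_distance(c(0.3, 0.4), c(0, 0)), 0.5)
  d1 <- adaptive_distance(c(0.3, 0.4), c(0, 0), scales = c(1, 1))
  d2 <- adaptive_distance(c(0.3, 0.4), c(0, 0), scales = c(2, 2))
  expect_equal(d2, d1 / 2)
  expect_error(adaptive_distance(c(0.1), c(0.1, 0.2)), "length")
  t1 <- trajectory(c(0, 10), c(0, 0.5))
  t2 <- trajectory(c(0, 20), c(0, 0.5))
  expect_error(adaptive_distance(t1, t2), "grids")
})

test_that("SMC matches the analytic posterior on a conjugate toy problem", {
  n <- 20; k_obs <- 14
  prior <- structure(list(lower = 0, upper = 1, names = "theta"),
                     class = "prior_spec")
  sim <- function(th) rbinom(1, n, th) / n
  post <- abc_smc(k_obs / n, sim, prior, budget = 2000, seed = 42)
  # analytic posterior is Beta(k+1, n-k+1)
  ana_mean <- (k_obs + 1) / (n + 2)
  pm <- weighted.mean(post$samples[, 1], post$weights)
  ess <- 1 / sum(post$weights^2)
  wsd <- sqrt(weighted.mean((post$samples[, 1] - pm)^2, post$weights))
  expect_lt(abs(pm - ana_mean), 3 * wsd / sqrt(ess) + 0.02)
  expect_gte(ess, 50)
})

test_that("SMC bookkeeping: shrinking thresholds, support, determinism", {
  m <- wf_handle()
  obs <- m$simulate(1e-5, 0.1, seed = 99)
  post <- abc_smc(obs, m, prior_spec(), budget = 1000, seed = 7)
  eps <- post$diagnostics$epsilons
  expect_true(all(diff(eps) <= 1e-12))
  expect_true(all(cnvsbi:::in_support(prior_spec(), post$samples)))
  expect_gte(1 / sum(post$weights^2), 50)
  # MAP within one order of magnitude of the generating parameters
  mp <- map_estimate(post)
  expect_lt(abs(log_ratio(mp["delta_c"], 1e-5)), 1)
  expect_lt(abs(log_ratio(mp["s_c"], 0.1)), 1)
  # bit-identical repeat under the same seed
  post2 <- abc_smc(obs, m, prior_spec(), budget = 1000, seed = 7)
  expect_identical(post$samples, post2$samples)
  expect_identical(post$weights, post2$weights)
})

test_that("a point prior collapses the posterior to that point", {
  prior <- structure(list(lower = c(-5, -1), upper = c(-5, -1),
                          names = c("log10_delta_c", "log10_s_c")),
                     class = "prior_spec")
  post <- abc_smc(c(0.5, 0.5), function(th) c(0, 0), prior,
                  budget = 100, seed = 1)
  expect_true(all(post$samples[, 1] == -5))
  expect_true(all(post$samples[, 2] == -1))
})
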