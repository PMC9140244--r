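test_that("MAP finds the mode of known sampling distributions", {
  set.seed(10)
  s <- cbind(rnorm(20000, -5, 0.3), rnorm(20000, -1, 0.2))
  post <- sample_posterior_fixture(s, lower = c(-12, -4), upper = c(0, 0))
  mp <- map_estimate(post, natural = FALSE)
  expect_lt(max(abs(mp - c(-5, -1))), 0.05)
  # a degenerate posterior returns its point
  pt <- sample_posterior_fixture(matrix(c(-5, -1), 100, 2, byrow = TRUE),
                                 lower = c(-12, -4), upper = c(0, 0))
  expect_equal(unname(map_estimate(pt, natural = FALSE)), c(-5, -1))
})

test_that("MAP picks the denser mode of a bimodal equal-mass sample", {
  set.seed(11)
  tight <- cbind(rnorm(2500, -8, 0.1), rnorm(2500, -3, 0.1))
  wide <- cbind(rnorm(2500, -4, 0.8), rnorm(2500, -1, 0.8))
  s <- rbind(tight, wide)
  post <- sample_posterior_fixture(s, lower = c(-12, -5), upper = c(0, 1))
  # brute-force KDE grid oracle: the tighter mode has the higher density
  f <- cnvsbi:::posterior_logdensity_fn(post)
  expect_gt(f(rbind(c(-8, -3))), f(rbind(c(-4, -1))))
  mp <- map_estimate(post, natural = FALSE)
  expect_lt(max(abs(mp - c(-8, -3))), 0.3)
})

test_that("HDI is the shortest interval with the requested mass", {
  set.seed(12)
  u <- runif(1e5)
  expect_equal(diff(hdi(u)), 0.95, tolerance = 0.02)
  z <- rnorm(1e5)
  expect_equal(diff(hdi(z)), 2 * qnorm(0.975), tolerance = 0.02 * 3.92)
  expect_equal(diff(hdi(rep(0.3, 200))), 0)
  expect_error(hdi(u, level = 1.2), "level")
})

test_that("HDR membership follows the density-quantile rule and nests", {
  set.seed(13)
  s <- cbind(rnorm(4000, -6, 0.5), rnorm(4000, -2, 0.25))
  post <- sample_posterior_fixture(
    s, lower = c(-12, -4), upper = c(0, 0),
    names = c("log10_delta_c", "log10_s_c"))
  # the MAP itself is inside every HDR
  mp <- map_estimate(post, natural = FALSE)
  for (lev in c(0.5, 0.95))
    expect_true(hdr_contains(post, mp, lev, natural = FALSE))
  # a point far outside is in none
  expect_false(hdr_contains(post, c(-11.5, -3.9), 0.95, natural = FALSE))
  # chi-square radius oracle: a point at the Mahalanobis radius enclosing
  # 60% of a bivariate normal lies inside the 95% but outside the 50% HDR
  r60 <- sqrt(qchisq(0.6, df = 2))
  pt <- c(-6 + 0.5 * r60, -2)
  expect_true(hdr_contains(post, pt, 0.95, natural = FALSE))
  expect_false(hdr_contains(post, pt, 0.5, natural = FALSE))
  # nesting over random probe points
  for (i in 1:20) {
    probe <- c(runif(1, -8, -4), runif(1, -3, -1))
    if (hdr_contains(post, probe, 0.5, natural = FALSE))
      expect_true(hdr_contains(post, probe, 0.95, natural = FALSE))
  }
})

test_that("log ratio is the base-10 log of estimate over truth", {
  expect_equal(log_ratio(1e-5, 1e-5), 0)
  expect_equal(log_ratio(1e-4, 1e-5), 1)
  expect_equal(log_ratio(0.025, 0.1), log10(0.25))
  expect_error(log_ratio(-1, 1), "positive")
})

test_that("posterior predictive checks score simulations against the data", {
  grid <- c(0, 50, 100, 150)
  obs <- trajectory(grid, c(0, 0.2, 0.6, 0.9))
  pt <- sample_posterior_fixture(
    matrix(c(-5, -1), 200, 2, byrow = TRUE), lower = c(-12, -4),
    upper = c(0, 0), names = c("log10_delta_c", "log10_s_c"))
  # perfect predictions
  m_id <- stub_model(grid, function(theta) obs$proportion)
  ppc <- posterior_predict(pt, m_id, obs, n_draws = 10, seed = 1)
  expect_equal(unname(ppc$summary["rmse", "mean"]), 0)
  expect_equal(unname(ppc$map_rmse), 0)
  expect_equal(unname(ppc$map_corr), 1)
  # constant offset: rmse is the offset, correlation still 1
  m_off <- stub_model(grid, function(theta) obs$proportion + 0.1)
  ppc2 <- posterior_predict(pt, m_off, obs, n_draws = 10, seed = 1)
  expect_equal(unname(ppc2$map_rmse), 0.1, tolerance = 1e-12)
  expect_equal(unname(ppc2$map_corr), 1, tolerance = 1e-12)
  # constant predictions make the correlation undefined, not zero
  m_const <- stub_model(grid, function(theta) rep(0.5, length(grid)))
  ppc3 <- posterior_predict(pt, m_const, obs, n_draws = 5, seed = 1)
  expect_true(is.na(ppc3$map_corr))
})

test_that("MAP prediction error does not exceed the worst posterior draw", {
  npe <- small_npe()
  m <- wf_handle()
  obs <- m$simulate(1e-5, 0.1, seed = 99)
  post <- predict(npe, obs, seed = 3)
  ppc <- posterior_predict(post, m, obs, n_draws = 20, seed = 8)
  expect_lte(ppc$map_rmse, max(ppc$rmse))
})

test_that("AIC and both WAIC formulas are computed exactly", {
  grid <- c(0, 50, 100)
  obs <- trajectory(grid, c(0, 0.3, 0.8))
  pt <- sample_posterior_fixture(
    matrix(c(-5, -1), 200, 2, byrow = TRUE), lower = c(-12, -4),
    upper = c(0, 0), names = c("log10_delta_c", "log10_s_c"))
  m_id <- stub_model(grid, function(theta) obs$proportion)
  ic <- information_criteria(pt, m_id, obs, n_draws = 5, n_rep = 10,
                             seed = 2)
  # deterministic perfect simulator: per-point surrogate is
  # N(y_t, sd_floor), so the AIC is known in closed form
  ll <- sum(dnorm(0, 0, 1e-3, log = TRUE)) * length(grid)
  expect_equal(unname(ic["aic"]), -2 * ll + 4, tolerance = 1e-10)
  # constant pointwise likelihood across draws: both penalties vanish
  ll_const <- matrix(log(0.7), nrow = 4, ncol = 6)
  w <- cnvsbi:::waic_from_loglik(ll_const)
  expect_equal(unname(w["waic1"]), -2 * 4 * log(0.7), tolerance = 1e-12)
  expect_equal(unname(w["waic2"]), -2 * 4 * log(0.7), tolerance = 1e-12)
  expect_equal(unname(w["waic1"] - w["waic2"]), 0, tolerance = 1e-12)
})

test_that("WAIC matches an independent transcription of the formulas", {
  set.seed(77)
  ll <- matrix(rnorm(25 * 40, -2, 1), 25, 40)  # n_obs x S
  ours <- cnvsbi:::waic_from_loglik(ll)
  # literal transcription of the two formulas, coded term by term
  w1 <- -2 * sum(log(rowMeans(exp(ll)))) +
    2 * sum(log(rowMeans(exp(ll))) - rowMeans(ll))
  w2 <- -2 * sum(log(rowMeans(exp(ll)))) +
    2 * sum(apply(ll, 1, function(v) sum((v - mean(v))^2) / (length(v) - 1)))
  expect_lt(abs(ours["waic1"] - w1), 1e-10)
  expect_lt(abs(ours["waic2"] - w2), 1e-10)
})
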