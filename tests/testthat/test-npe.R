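test_that("training sets are reproducible and prior draws are log-uniform", {
  m <- wf_handle()
  a <- generate_training_set(prior_spec(), m, 500, seed = 13)
  b <- generate_training_set(prior_spec(), m, 500, seed = 13)
  expect_identical(a$thetas, b$thetas)
  expect_identical(a$xs, b$xs)
  ts <- small_train()
  # marginal of log10 delta_c is uniform on [-12, -3]
  ks <- suppressWarnings(ks.test(ts$thetas[, 1], "punif", -12, -3))
  expect_gt(ks$p.value, 0.01)
  # small-rate draws yield at least one all-zero trajectory
  expect_gte(sum(rowSums(ts$xs) == 0), 1)
  expect_true(all(cnvsbi:::in_support(prior_spec(), ts$thetas)))
})

test_that("the amortized posterior is a proper density on the prior box", {
  npe <- small_npe()
  m <- wf_handle()
  obs <- m$simulate(1e-5, 0.1, seed = 99)
  post <- predict(npe, obs, seed = 3)
  pr <- prior_spec()
  g1 <- seq(pr$lower[1], pr$upper[1], length.out = 300)
  g2 <- seq(pr$lower[2], pr$upper[2], length.out = 300)
  gg <- as.matrix(expand.grid(g1, g2))
  integ <- sum(exp(post$log_density(gg))) * diff(g1[1:2]) * diff(g2[1:2])
  expect_equal(integ, 1, tolerance = 0.05)
  # samples respect the prior support
  expect_true(all(cnvsbi:::in_support(pr, post$samples)))
  # outside the box the density vanishes
  expect_identical(post$log_density(rbind(c(-2, 0))), -Inf)
  # the same seed materializes the same draws
  post2 <- predict(npe, obs, seed = 3)
  expect_identical(post$samples, post2$samples)
})

test_that("evaluating new observations costs no additional simulations", {
  npe <- small_npe()
  m <- wf_handle()
  o1 <- m$simulate(1e-5, 0.1, seed = 1)
  o2 <- m$simulate(1e-6, 0.05, seed = 2)
  before <- n_sim_calls(m)
  p1 <- predict(npe, o1, seed = 5)
  p2 <- predict(npe, o2, seed = 6)
  expect_identical(n_sim_calls(m), before)
  expect_false(identical(p1$samples, p2$samples))
})

test_that("well-identified observations are recovered with truth in the 95% HDR", {
  npe <- bench_npe()
  m <- wf_handle()
  obs <- m$simulate(1e-5, 0.1, seed = 99)
  post <- predict(npe, obs, seed = 3)
  expect_true(hdr_contains(post, c(delta_c = 1e-5, s_c = 0.1), 0.95))
  mp <- map_estimate(post)
  expect_lt(abs(log_ratio(mp["delta_c"], 1e-5)), 0.5)
  expect_lt(abs(log_ratio(mp["s_c"], 0.1)), 0.2)
})

test_that("independently trained estimators agree on benchmark MAPs", {
  m <- wf_handle()
  obs <- m$simulate(1e-5, 0.1, seed = 99)
  maps <- sapply(1:3, function(i) {
    ts <- generate_training_set(prior_spec(), m, 2000,
                                seed = cnvsbi:::child_seed(400, i))
    np <- fit_npe(ts, K = 6, hidden = c(64, 64), epochs = 120,
                  patience = 20, seed = 500 + i)
    log10(map_estimate(predict(np, obs, seed = 9)))
  })
  for (i in 1:2) for (j in (i + 1):3)
    expect_lt(max(abs(maps[, i] - maps[, j])), 1)
})

test_that("the autoregressive-Gaussian estimator satisfies the same contracts", {
  ts <- small_train()
  npe <- fit_npe(ts, estimator = "maf", hidden = c(64, 64), epochs = 100,
                 patience = 20, seed = 15)
  m <- wf_handle()
  obs <- m$simulate(1e-5, 0.1, seed = 99)
  post <- predict(npe, obs, seed = 3)
  pr <- prior_spec()
  expect_true(all(cnvsbi:::in_support(pr, post$samples)))
  g1 <- seq(pr$lower[1], pr$upper[1], length.out = 250)
  g2 <- seq(pr$lower[2], pr$upper[2], length.out = 250)
  gg <- as.matrix(expand.grid(g1, g2))
  integ <- sum(exp(post$log_density(gg))) * diff(g1[1:2]) * diff(g2[1:2])
  expect_equal(integ, 1, tolerance = 0.05)
  expect_true(all(is.finite(map_estimate(post, natural = FALSE))))
})

test_that("observation-set estimator: summary contract and joint inference", {
  hn <- hier_npe()
  suite <- make_dfe_suite(gamma_dfe(1, 0.1), 1e-5, seed = 33)
  obs8 <- lapply(suite$observations[1:8], `[[`, "trajectory")
  s1 <- summarize_observation_set(hn, obs8)
  s2 <- summarize_observation_set(hn, obs8)
  expect_identical(s1, s2)
  expect_length(s1, 5)
  expect_error(summarize_observation_set(hn, obs8[1:5]), "exactly 8")
  post <- predict(hn, obs8, seed = 4)
  expect_true(all(cnvsbi:::in_support(hier_prior(), post$samples)))
  mp <- map_estimate(post)
  expect_named(mp, c("alpha", "beta", "delta_c"))
  expect_true(all(is.finite(mp)))
})
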