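test_that("mutation step matches the three-genotype equations", {
  p <- evolution_params(delta_c = 0.1, s_c = 0, delta_b = 0.05, s_b = 0)
  expect_equal(mutate_step(c(1, 0, 0), p), c(0.85, 0.05, 0.10))
  # no mutation leaves any state unchanged
  p0 <- evolution_params(0, 0.2, 0, 0.01)
  st <- c(0.4, 0.35, 0.25)
  expect_equal(mutate_step(st, p0), st)
  # hand substitution at realistic rates
  p2 <- evolution_params(1e-5, 0, 1e-5, 0)
  st2 <- c(0.5, 0.25, 0.25)
  expect_equal(mutate_step(st2, p2),
               c((1 - 2e-5) * 0.5, 0.5 * 1e-5 + 0.25, 0.5 * 1e-5 + 0.25),
               tolerance = 1e-15)
  expect_equal(sum(mutate_step(st2, p2)), 1, tolerance = 1e-12)
})

test_that("selection step renormalizes by mean fitness", {
  p <- evolution_params(0, 0.1, 0, 0)
  out <- selection_step(c(0.5, 0, 0.5), p)
  expect_equal(out[3], 0.55 / 1.05, tolerance = 1e-12)
  expect_equal(sum(out), 1, tolerance = 1e-12)
  # neutral identity
  pn <- evolution_params(0, 0, 0, 0)
  st <- c(0.2, 0.5, 0.3)
  expect_equal(selection_step(st, pn), st)
  # hand-computed normalization with both classes selected
  p2 <- evolution_params(0, 0.1, 0, 0.001)
  w <- c(1, 1.001, 1.1)
  st3 <- rep(1 / 3, 3)
  expect_equal(selection_step(st3, p2), w * st3 / sum(w * st3),
               tolerance = 1e-12)
})

test_that("drift is a single multinomial resample", {
  p <- evolution_params(0, 0, 0, 0)
  # degenerate state is absorbing
  set.seed(1)
  expect_equal(drift_step(c(1, 0, 0), 100), c(1, 0, 0))
  # determinism under a fixed seed
  set.seed(42); a <- drift_step(c(0.5, 0.3, 0.2), 1000)
  set.seed(42); b <- drift_step(c(0.5, 0.3, 0.2), 1000)
  expect_identical(a, b)
  expect_error(drift_step(c(0.5, 0.3, 0.2), 10.5), "integer")
  # variance oracle: var(x_C') = p(1-p)/N
  N <- 1000; pc <- 0.2
  set.seed(7)
  xs <- replicate(10000, drift_step(c(0.5, 0.3, pc), N)[3])
  expect_equal(mean(xs), pc, tolerance = 0.01)
  # chi-square bounds on the sample variance at alpha = 0.01
  s2 <- var(xs); sig2 <- pc * (1 - pc) / N
  stat <- (length(xs) - 1) * s2 / sig2
  expect_gt(stat, qchisq(0.005, length(xs) - 1))
  expect_lt(stat, qchisq(0.995, length(xs) - 1))
})

test_that("wf simulation: no mutation means no CNVs; fixed seed repeats", {
  p0 <- evolution_params(0, 0.1, 0, 0.001)
  tr <- simulate_wf(p0, N = 1e5, sample_times = seq(0, 100, by = 10),
                    seed = 3)
  expect_true(all(tr$proportion == 0))
  p <- evolution_params(1e-5, 0.1)
  a <- simulate_wf(p, N = 1e6, seed = 9)
  b <- simulate_wf(p, N = 1e6, seed = 9)
  expect_identical(a$proportion, b$proportion)
  expect_error(simulate_wf(p, sample_times = numeric(0)), "non-empty")
})

test_that("frequencies stay on the simplex through composed steps", {
  set.seed(5)
  p <- evolution_params(1e-3, 0.2, 1e-4, 0.01)
  st <- c(0.9, 0.06, 0.04)
  for (i in 1:200) {
    st <- drift_step(selection_step(mutate_step(st, p), p), 5000)
    expect_true(all(st >= 0))
    expect_lt(abs(sum(st) - 1), 1e-9)
  }
})

test_that("large-N simulation matches the deterministic recursion", {
  p <- evolution_params(1e-5, 0.1)
  det <- cnvsbi:::wf_deterministic(p, 267)
  grid <- default_grid()
  # seed-averaged mean trajectory agrees with the infinite-N recursion
  reps <- sapply(1:5, function(r)
    simulate_wf(p, N = 3.3e8, sample_times = grid,
                seed = cnvsbi:::child_seed(21, r))$proportion)
  expect_lt(max(abs(rowMeans(reps) - det[round(grid) + 1])), 1e-3)
  # sigmoidal sweep: near fixation by ~130 generations
  expect_gt(det[134], 0.95)
  expect_gt(min(reps[which.min(abs(grid - 133)), ]), 0.9)
})

test_that("mean final proportion is monotone in the selection coefficient", {
  s_grid <- c(0.02, 0.05, 0.1, 0.2)
  means <- sapply(seq_along(s_grid), function(i) {
    mean(sapply(1:100, function(r)
      simulate_wf(evolution_params(1e-4, s_grid[i]), N = 1e5,
                  sample_times = c(0, 150),
                  seed = cnvsbi:::child_seed(77, i * 1000 + r))$proportion[2]))
  })
  expect_true(all(diff(means) >= 0))
})

test_that("replicate spread after establishment is small relative to the mean", {
  grid <- default_grid()
  reps <- sapply(1:5, function(r)
    simulate_wf(evolution_params(1e-5, 0.1), N = 3.3e8,
                sample_times = grid,
                seed = cnvsbi:::child_seed(31, r))$proportion)
  late <- grid >= 150  # past establishment
  cv <- apply(reps[late, ], 1, sd) / rowMeans(reps[late, ])
  expect_lt(max(cv), 0.05)
})
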