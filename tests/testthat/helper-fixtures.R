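# Shared fixtures. The amortized estimators are expensive to train, so they
# are built once per test process and cached (tests run in one process, in
# file order). Cache lives in an option so re-sourcing helpers cannot drop it.

test_cache <- function() {
  cache <- getOption("cnvsbi.test.cache")
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    options(cnvsbi.test.cache = cache)
  }
  cache
}

cache_get <- function(name, expr) {
  cache <- test_cache()
  if (is.null(cache[[name]])) cache[[name]] <- force(expr)
  cache[[name]]
}

# Wright-Fisher simulator handle on the standard grid.
wf_handle <- function() cache_get("wf_handle", cnv_model("wf"))

chemo_handle <- function() cache_get("chemo_handle", cnv_model("chemo"))

# The benchmark amortized estimator: 10,000 Wright-Fisher training
# simulations, package-default settings.
bench_train <- function() cache_get(
  "bench_train",
  generate_training_set(prior_spec(), wf_handle(), 10000, seed = 101))

bench_npe <- function() cache_get(
  "bench_npe", fit_npe(bench_train(), seed = 202))

# 20 Wright-Fisher benchmark observations (4 combos x 5 replicates).
bench_suite <- function() cache_get(
  "bench_suite", make_grid_suite(models = "wf", seed = 303))

# A small, fast estimator for contract-level tests.
small_train <- function() cache_get(
  "small_train",
  generate_training_set(prior_spec(), wf_handle(), 2000, seed = 11))

small_npe <- function() cache_get(
  "small_npe",
  fit_npe(small_train(), K = 6, hidden = c(64, 64), epochs = 120,
          patience = 20, seed = 5))

# Hierarchical (observation-set) estimator at test scale.
hier_npe <- function() cache_get("hier_npe", {
  hts <- generate_set_training_set(wf_handle(), 3000, seed = 55)
  fit_npe_set(hts, seed = 66)
})

# A posterior object built from explicit weighted samples (for metric
# tests that need known sampling distributions).
sample_posterior_fixture <- function(samples, weights = NULL,
                                     lower = apply(samples, 2, min),
                                     upper = apply(samples, 2, max),
                                     names = paste0("par", seq_len(ncol(samples)))) {
  prior <- structure(list(lower = lower, upper = upper, names = names),
                     class = "prior_spec")
  cnvsbi:::new_posterior(samples, weights, prior = prior, method = "fixture")
}

# A deterministic stand-in simulator handle whose simulate_vec returns a
# fixed function of theta; used to probe the assessment machinery.
stub_model <- function(grid, fn) {
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  structure(list(model = "stub", grid = grid,
                 simulate_vec = function(theta) {
                   counter$n <- counter$n + 1L
                   fn(theta)
                 },
                 simulate = function(delta_c, s_c, seed = NULL) {
                   trajectory(grid, fn(c(log10(delta_c), log10(s_c))))
                 },
                 counter = counter),
            class = "cnv_model")
}
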