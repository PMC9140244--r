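#' Single-generation steps of the Wright-Fisher model
#'
#' The per-generation update is mutation, then viability selection, then
#' multinomial drift. `state` is a length-3 frequency vector
#' `c(x_a, x_b, x_c)` (ancestral, other-beneficial, focal CNV) summing to 1.
#'
#' Mutation moves mass out of the ancestral class only (cells carry at most
#' one beneficial mutation):
#' `x_a' = (1 - delta_b - delta_c) x_a`, `x_b' = x_a delta_b + x_b`,
#' `x_c' = x_a delta_c + x_c`. Selection reweights by relative fitness
#' `w = (1, 1 + s_b, 1 + s_c)` and renormalises by the mean fitness. Drift
#' resamples counts from a single multinomial with `N` trials.
#'
#' @param state Length-3 numeric frequency vector summing to 1.
#' @param params An [evolution_params()] object.
#' @param N Population size (positive integer-valued scalar).
#'
#' @return A length-3 frequency vector.
#' @examples
#' p <- evolution_params(delta_c = 0.1, s_c = 0.1, delta_b = 0.05, s_b = 0)
#' mutate_step(c(1, 0, 0), p)
#' @export
mutate_step <- function(state, params) {
  check_state(state)
  c((1 - params$delta_b - params$delta_c) * state[1],
    state[1] * params$delta_b + state[2],
    state[1] * params$delta_c + state[3])
}

#' @rdname mutate_step
#' @export
selection_step <- function(state, params) {
  check_state(state)
  w <- c(1, 1 + params$s_b, 1 + params$s_c)
  wbar <- sum(w * state)
  if (wbar <= 0) stop("mean fitness is non-positive: invalid fitness configuration")
  w * state / wbar
}

#' @rdname mutate_step
#' @export
drift_step <- function(state, N, params = NULL) {
  check_state(state)
  if (length(N) != 1 || !is.finite(N) || N < 1 || N != floor(N))
    stop("N must be a positive integer")
  # rmultinom is limited to integer sizes; large N uses the same
  # conditional-binomial decomposition as the compiled simulator
  if (N <= .Machine$integer.max) {
    counts <- as.numeric(rmultinom(1, size = N, prob = state))
  } else {
    na <- rbinom(1, size = N, prob = state[1])
    pb <- if (state[1] >= 1) 0 else min(1, state[2] / (1 - state[1]))
    nb <- if (N - na > 0) rbinom(1, size = N - na, prob = pb) else 0
    counts <- c(na, nb, N - na - nb)
  }
  counts / N
}

check_state <- function(state) {
  if (length(state) != 3 || any(!is.finite(state)))
    stop("state must be a finite length-3 vector")
  if (any(state < -1e-12) || abs(sum(state) - 1) > 1e-9)
    stop("state must be non-negative frequencies summing to 1")
  invisible(state)
}

#' Simulate focal-CNV dynamics under the Wright-Fisher model
#'
#' Forward simulation of three genotype classes (ancestral, other
#' beneficial, focal CNV) with discrete, non-overlapping generations and a
#' constant population size. Each generation applies [mutate_step()],
#' [selection_step()] and [drift_step()] in that order; the population
#' starts fully ancestral. The default `N = 3.3e8` is the effective
#' population size estimated for the chemostat conditions this model
#' approximates (see [estimate_ne()]).
#'
#' @param params An [evolution_params()] object.
#' @param N Population size (default `3.3e8`).
#' @param sample_times Generation grid on which to record the focal-CNV
#'   proportion; non-integer times are rounded to the nearest generation.
#'   Defaults to [default_grid()].
#' @param seed Optional integer seed for exact reproducibility.
#'
#' @return A [trajectory()] with the focal-CNV proportion at each sample
#'   time.
#' @examples
#' tr <- simulate_wf(evolution_params(1e-5, 0.1), N = 1e6,
#'                   sample_times = seq(0, 100, by = 20), seed = 1)
#' tr
#' @export
simulate_wf <- function(params, N = 3.3e8, sample_times = default_grid(),
                        seed = NULL) {
  stopifnot(inherits(params, "evolution_params"))
  if (length(sample_times) == 0) stop("sample_times must be non-empty")
  if (any(sample_times < 0)) stop("sample_times must be non-negative")
  with_seed(seed)
  gens <- as.integer(round(sample_times))
  n_gen <- max(gens)
  path <- wf_core(params$delta_c, params$s_c, params$delta_b, params$s_b,
                  N, n_gen)
  trajectory(sample_times, path[gens + 1])
}

# Deterministic (infinite-N) recursion of the same model; oracle for the
# large-N limit and workhorse for shape checks.
wf_deterministic <- function(params, n_gen) {
  x <- c(1, 0, 0)
  w <- c(1, 1 + params$s_b, 1 + params$s_c)
  xc <- numeric(n_gen + 1)
  for (g in seq_len(n_gen)) {
    x <- c((1 - params$delta_b - params$delta_c) * x[1],
           x[1] * params$delta_b + x[2],
           x[1] * params$delta_c + x[3])
    x <- w * x / sum(w * x)
    xc[g + 1] <- x[3]
  }
  xc
}
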