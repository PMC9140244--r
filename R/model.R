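#' Simulator handle for inference
#'
#' Wraps one of the two evolutionary simulators as a model over the two
#' inferred parameters `(delta_c, s_c)`, with the nuisance parameters
#' (other-beneficial mutation rate and effect, population size or chemostat
#' constants, sampling grid) fixed at construction. The handle counts its
#' simulator calls, which makes the amortization property of neural
#' posterior estimation directly checkable.
#'
#' @param model `"wf"` (Wright-Fisher) or `"chemo"` (stochastic chemostat).
#' @param sample_times Generation grid for all simulations; defaults to
#'   [default_grid()].
#' @param N Wright-Fisher population size (default `3.3e8`, the effective
#'   size of the chemostat conditions).
#' @param cparams [chemostat_params()] for the chemostat simulator.
#' @param delta_b,s_b Rate and selection coefficient of the pooled other
#'   beneficial mutations (defaults `1e-5` and `0.001`).
#' @param tau Tau-leap step (hours) for the chemostat simulator.
#'
#' @return An object of class `"cnv_model"` with elements `simulate(delta_c,
#'   s_c, seed)` returning a [trajectory()], `simulate_vec(theta)` taking
#'   `(log10 delta_c, log10 s_c)` and returning the proportion vector, and
#'   `grid`.
#' @examples
#' m <- cnv_model("wf", sample_times = c(0, 50, 100), N = 1e6)
#' m$simulate(1e-4, 0.1, seed = 1)
#' n_sim_calls(m)
#' @export
cnv_model <- function(model = c("wf", "chemo"),
                      sample_times = default_grid(), N = 3.3e8,
                      cparams = chemostat_params(), delta_b = 1e-5,
                      s_b = 0.001, tau = 0.1) {
  model <- match.arg(model)
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  grid <- as.numeric(sample_times)
  simulate_vec <- if (model == "wf") {
    gens <- as.integer(round(grid))
    n_gen <- max(gens)
    function(theta) {
      counter$n <- counter$n + 1L
      path <- wf_core(10^theta[1], 10^theta[2], delta_b, s_b, N, n_gen)
      path[gens + 1]
    }
  } else {
    hours <- generation_to_hours(grid, cparams)
    function(theta) {
      counter$n <- counter$n + 1L
      ep <- evolution_params(10^theta[1], 10^theta[2], delta_b, s_b)
      res <- chemo_core(ep$delta_c, ep$s_c, ep$delta_b, ep$s_b,
                        cparams$dilution_rate, cparams$s0, cparams$k,
                        cparams$yield, cparams$mu_max, cparams$volume,
                        cparams$inoculum, 0, tau, hours)
      tot <- res$n_a + res$n_b + res$n_c
      ifelse(tot > 0, pmin(1, res$n_c / tot), 0)
    }
  }
  obj <- list(
    model = model, grid = grid, N = N, cparams = cparams,
    delta_b = delta_b, s_b = s_b, tau = tau,
    simulate_vec = simulate_vec,
    simulate = function(delta_c, s_c, seed = NULL) {
      with_seed(seed)
      trajectory(grid, simulate_vec(c(log10(delta_c), log10(s_c))))
    },
    counter = counter)
  class(obj) <- "cnv_model"
  obj
}

#' @rdname cnv_model
#' @param x A `cnv_model`.
#' @export
n_sim_calls <- function(x) {
  stopifnot(inherits(x, "cnv_model"))
  x$counter$n
}

#' @export
print.cnv_model <- function(x, ...) {
  cat(sprintf("CNV simulator handle: %s model, %d time points (gen %g-%g)\n",
              x$model, length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("  nuisance: delta_b = %.3g, s_b = %.3g; calls so far: %d\n",
              x$delta_b, x$s_b, n_sim_calls(x)))
  invisible(x)
}
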