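#' Evolutionary parameters for both simulators
#'
#' Bundles the four parameters that drive both the Wright-Fisher and the
#' chemostat simulator: the formation rate and selection coefficient of the
#' focal mutation class (CNVs at the reporter locus), and of the pooled
#' "other beneficial mutations" class.
#'
#' @param delta_c Focal-CNV formation rate per cell division (probability).
#' @param s_c Focal-CNV selection coefficient per generation.
#' @param delta_b Other-beneficial formation rate per cell division.
#'   Default `1e-5`.
#' @param s_b Other-beneficial selection coefficient per generation.
#'   Default `0.001`.
#'
#' @return An object of class `"evolution_params"` (a named list).
#' @examples
#' evolution_params(delta_c = 1e-5, s_c = 0.1)
#' @export
evolution_params <- function(delta_c, s_c, delta_b = 1e-5, s_b = 0.001) {
  stopifnot(is.numeric(delta_c), is.numeric(s_c),
            is.numeric(delta_b), is.numeric(s_b))
  if (delta_c < 0 || delta_b < 0)
    stop("formation rates must be non-negative")
  if (delta_c + delta_b > 1)
    stop("delta_c + delta_b must not exceed 1")
  if (s_c <= -1 || s_b <= -1)
    stop("selection coefficients must exceed -1")
  structure(list(delta_c = delta_c, s_c = s_c,
                 delta_b = delta_b, s_b = s_b),
            class = "evolution_params")
}

#' @export
print.evolution_params <- function(x, ...) {
  cat("Evolutionary parameters:\n")
  cat(sprintf("  focal CNV:        delta_c = %.3g, s_c = %.3g\n",
              x$delta_c, x$s_c))
  cat(sprintf("  other beneficial: delta_b = %.3g, s_b = %.3g\n",
              x$delta_b, x$s_b))
  invisible(x)
}

#' Chemostat device and growth parameters
#'
#' Constants describing the chemostat and the ancestral strain's growth
#' kinetics. Defaults are the glutamine-limited chemostat conditions of the
#' experimental system: dilution rate 0.12/h, feed concentration 0.8 mM,
#' Monod constant 0.103 mM, yield 32,445,000 cells/mL/mM and maximal growth
#' rate 0.35/h. The default working volume of 20 mL puts the steady-state
#' census near 5e8 cells, and generations are counted after a 48-h burn-in
#' during which the vessel approaches steady state.
#'
#' @param dilution_rate Dilution rate D (per hour); must satisfy
#'   `0 < D < mu_max`.
#' @param s0 Limiting-nutrient concentration in the feed (mM).
#' @param k Half-saturation (Monod) constant (mM), shared by all genotypes.
#' @param yield Cell yield per mM of limiting nutrient (cells/mL/mM).
#' @param mu_max Ancestral maximal growth rate (per hour).
#' @param volume Culture volume (mL).
#' @param inoculum Initial number of ancestral cells.
#' @param burn_in_h Hours before generation counting starts.
#'
#' @return An object of class `"chemostat_params"` (a named list).
#' @examples
#' chemostat_params()
#' @export
chemostat_params <- function(dilution_rate = 0.12, s0 = 0.8, k = 0.103,
                             yield = 32445000, mu_max = 0.35, volume = 20,
                             inoculum = 1.5e7, burn_in_h = 48) {
  stopifnot(dilution_rate > 0, s0 > 0, k > 0, yield > 0, volume > 0,
            inoculum >= 1, burn_in_h >= 0)
  if (dilution_rate >= mu_max)
    stop("dilution rate must be below mu_max (washout otherwise)")
  structure(list(dilution_rate = dilution_rate, s0 = s0, k = k,
                 yield = yield, mu_max = mu_max, volume = volume,
                 inoculum = inoculum, burn_in_h = burn_in_h),
            class = "chemostat_params")
}

#' @export
print.chemostat_params <- function(x, ...) {
  cat("Chemostat parameters:\n")
  cat(sprintf("  D = %.3g /h, S0 = %.3g mM, k = %.3g mM\n",
              x$dilution_rate, x$s0, x$k))
  cat(sprintf("  yield = %.4g cells/mL/mM, mu_max = %.3g /h\n",
              x$yield, x$mu_max))
  cat(sprintf("  volume = %.3g mL, inoculum = %.3g cells, burn-in = %g h\n",
              x$volume, x$inoculum, x$burn_in_h))
  cat(sprintf("  doubling time at steady state: %.3g h\n",
              log(2) / x$dilution_rate))
  invisible(x)
}

#' Prior bounds for the two inferred parameters
#'
#' Log-uniform priors for the focal-CNV formation rate (`1e-12` to `1e-3`)
#' and selection coefficient (`1e-4` to `0.4`). Inference operates on
#' `(log10 delta_c, log10 s_c)`, where these priors are uniform boxes.
#'
#' @param delta_c_bounds Length-2 numeric, natural-scale bounds for
#'   `delta_c`.
#' @param s_c_bounds Length-2 numeric, natural-scale bounds for `s_c`.
#'
#' @return An object of class `"prior_spec"` with elements `lower`/`upper`
#'   (log10-scale) and `names`.
#' @examples
#' prior_spec()
#' @export
prior_spec <- function(delta_c_bounds = c(1e-12, 1e-3),
                       s_c_bounds = c(1e-4, 0.4)) {
  stopifnot(length(delta_c_bounds) == 2, length(s_c_bounds) == 2,
            all(delta_c_bounds > 0), all(s_c_bounds > 0),
            delta_c_bounds[1] < delta_c_bounds[2],
            s_c_bounds[1] < s_c_bounds[2])
  structure(list(lower = log10(c(delta_c_bounds[1], s_c_bounds[1])),
                 upper = log10(c(delta_c_bounds[2], s_c_bounds[2])),
                 names = c("log10_delta_c", "log10_s_c")),
            class = "prior_spec")
}

# Uniform draws from the (log10-space) prior box; returns an n x d matrix.
sample_prior <- function(prior, n) {
  d <- length(prior$lower)
  m <- matrix(runif(n * d), ncol = d)
  m <- sweep(sweep(m, 2, prior$upper - prior$lower, "*"), 2, prior$lower, "+")
  colnames(m) <- prior$names
  m
}

# TRUE for rows inside the prior box (closed).
in_support <- function(prior, theta) {
  theta <- rbind(theta)
  ok <- rep(TRUE, nrow(theta))
  for (j in seq_along(prior$lower))
    ok <- ok & theta[, j] >= prior$lower[j] & theta[, j] <= prior$upper[j]
  ok
}
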