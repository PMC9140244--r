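#' Monod growth rate
#'
#' Saturating growth kinetics: `mu = mu_max * S / (k + S)`.
#'
#' @param s Limiting-nutrient concentration (mM), non-negative.
#' @param mu_max Maximal growth rate (per hour).
#' @param k Half-saturation constant (mM).
#' @return Growth rate (per hour), in `[0, mu_max)`.
#' @examples
#' monod_growth_rate(0.8, 0.35, 0.103)
#' @export
monod_growth_rate <- function(s, mu_max, k) {
  if (any(s < 0)) stop("substrate concentration must be non-negative")
  mu_max * s / (k + s)
}

#' Convert between per-generation selection coefficients and Malthusian rates
#'
#' The per-generation selection coefficient relates to hourly Malthusian
#' parameters by `s = (r - r_a) / (r_a * ln 2)`, so
#' `r = r_a * (1 + s * ln 2)`.
#'
#' @param s Per-generation selection coefficient.
#' @param r_a Ancestral Malthusian parameter (per hour).
#' @param r Mutant Malthusian parameter (per hour).
#' @return `selection_to_malthusian()` returns `r`;
#'   `malthusian_to_selection()` returns `s`.
#' @examples
#' selection_to_malthusian(0.1, 0.35)
#' malthusian_to_selection(selection_to_malthusian(0.1, 0.35), 0.35)
#' @export
selection_to_malthusian <- function(s, r_a) {
  if (any(s <= -1 / log(2))) stop("s implies a negative growth rate")
  r_a * (1 + s * log(2))
}

#' @rdname selection_to_malthusian
#' @export
malthusian_to_selection <- function(r, r_a) (r - r_a) / (r_a * log(2))

#' Chemostat steady state
#'
#' At steady state the specific growth rate equals the dilution rate, so the
#' residual substrate solves `mu_max * S / (k + S) = D`, giving
#' `S* = D k / (mu_max - D)`, and the cell density is `Y (S0 - S*)`.
#'
#' @param cparams A [chemostat_params()] object.
#' @return A list with `s_star` (mM), `density` (cells/mL) and `census`
#'   (cells in the vessel, `density * volume`).
#' @examples
#' steady_state(chemostat_params())
#' @export
steady_state <- function(cparams) {
  stopifnot(inherits(cparams, "chemostat_params"))
  D <- cparams$dilution_rate
  if (D >= cparams$mu_max) stop("washout: no steady state for D >= mu_max")
  s_star <- D * cparams$k / (cparams$mu_max - D)
  if (s_star > cparams$s0)
    stop("washout: residual substrate would exceed the feed concentration")
  density <- cparams$yield * (cparams$s0 - s_star)
  list(s_star = s_star, density = density,
       census = density * cparams$volume)
}

#' Deterministic chemostat dynamics (ODE system)
#'
#' Integrates the mean-field equations for the three genotype counts and
#' the substrate:
#' `dn_i/dt = n_i (r_i S/(S+k) - D)` and
#' `dS/dt = (S0 - S) D - sum_i n_i r_i S / ((S+k) Y V)`,
#' with counts expressed as cells in the vessel (volume V). Mutation is
#' included as a fraction `delta` of ancestral births. Used as the drift
#' oracle for the stochastic tau-leap simulator and for steady-state
#' analytics.
#'
#' @param cparams A [chemostat_params()] object.
#' @param eparams An [evolution_params()] object (use zero rates for a pure
#'   growth curve).
#' @param hours Times (h) at which to report the state.
#' @return A data frame with columns `hours`, `n_a`, `n_b`, `n_c`, `s_mm`.
#' @export
chemostat_ode <- function(cparams, eparams = evolution_params(0, 0, 0, 0),
                          hours) {
  stopifnot(inherits(cparams, "chemostat_params"),
            inherits(eparams, "evolution_params"))
  r <- c(cparams$mu_max,
         selection_to_malthusian(eparams$s_b, cparams$mu_max),
         selection_to_malthusian(eparams$s_c, cparams$mu_max))
  rhs <- function(t, y, parms) {
    n <- y[1:3]; S <- max(y[4], 0)
    g <- n * r * S / (S + cparams$k)  # births/h per genotype
    births_a <- g[1]
    dn <- c(births_a * (1 - eparams$delta_b - eparams$delta_c),
            g[2] + births_a * eparams$delta_b,
            g[3] + births_a * eparams$delta_c) - n * cparams$dilution_rate
    dS <- (cparams$s0 - S) * cparams$dilution_rate -
      sum(g) / (cparams$yield * cparams$volume)
    list(c(dn, dS))
  }
  y0 <- c(cparams$inoculum, 0, 0, cparams$s0)
  times <- sort(unique(c(0, hours)))
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda")
  out <- as.data.frame(out)[match(hours, times), ]
  data.frame(hours = hours, n_a = out[[2]], n_b = out[[3]],
             n_c = out[[4]], s_mm = out[[5]])
}

#' Stochastic chemostat simulation (tau-leaping)
#'
#' Continuous-time stochastic simulation of three genotype classes in a
#' chemostat with Monod growth and constant dilution, using Poisson
#' tau-leaping over eight event channels (growth and dilution per genotype,
#' plus the two mutation channels coupled to ancestral births). The
#' substrate is a continuous state updated deterministically within each
#' leap from the sampled birth counts. Steps that would drive a count or
#' the substrate negative are retried at half the step, down to `tau/32`.
#'
#' Generations are counted after `burn_in_h` hours (default 48 h, roughly
#' the time needed to reach steady state): generation `g` corresponds to
#' `burn_in_h + g * ln(2) / D` hours.
#'
#' @param cparams A [chemostat_params()] object.
#' @param eparams An [evolution_params()] object.
#' @param sample_times Generation grid (>= 0) at which to record the
#'   focal-CNV proportion. Defaults to [default_grid()].
#' @param tau Leap length (hours), default 0.1 (about 1/58 of a doubling
#'   time).
#' @param seed Optional integer seed.
#'
#' @return A [trajectory()] of the focal-CNV proportion
#'   `n_c / (n_a + n_b + n_c)` at each sampled generation.
#' @examples
#' tr <- simulate_chemostat(chemostat_params(volume = 1, inoculum = 1e5),
#'                          evolution_params(1e-4, 0.1),
#'                          sample_times = c(0, 50, 100), seed = 1)
#' @export
simulate_chemostat <- function(cparams = chemostat_params(),
                               eparams,
                               sample_times = default_grid(),
                               tau = 0.1, seed = NULL) {
  st <- chemostat_run(cparams, eparams,
                      hours = generation_to_hours(sample_times, cparams),
                      tau = tau, seed = seed)
  total <- st$n_a + st$n_b + st$n_c
  if (any(total <= 0)) stop("total extinction during simulation")
  trajectory(sample_times, pmin(1, st$n_c / total))
}

#' @rdname simulate_chemostat
#' @param generations Generation values to convert to elapsed hours.
#' @export
generation_to_hours <- function(generations, cparams = chemostat_params()) {
  cparams$burn_in_h + generations * log(2) / cparams$dilution_rate
}

# Low-level stochastic run recording full state (counts + substrate) at the
# requested hours. init_frac_b seeds a fraction of the inoculum as genotype
# B (used for neutral two-lineage drift experiments).
chemostat_run <- function(cparams, eparams, hours, tau = 0.1,
                          init_frac_b = 0, seed = NULL) {
  stopifnot(inherits(cparams, "chemostat_params"),
            inherits(eparams, "evolution_params"),
            tau > 0, all(hours >= 0))
  if (any(diff(hours) < 0)) stop("hours must be non-decreasing")
  with_seed(seed)
  res <- chemo_core(eparams$delta_c, eparams$s_c, eparams$delta_b,
                    eparams$s_b, cparams$dilution_rate, cparams$s0,
                    cparams$k, cparams$yield, cparams$mu_max,
                    cparams$volume, cparams$inoculum, init_frac_b, tau,
                    as.numeric(hours))
  as.data.frame(res)
}

#' Estimate the effective population size from neutral drift
#'
#' Given a per-generation frequency series of a neutral allele, estimates
#' the effective population size from the conditional variance of the
#' next-generation frequency: `Ne = p(1-p) / mean(Var(p'|p))`, where the
#' per-generation conditional variance is estimated from the squared
#' frequency increments and `p(1-p)` is averaged over the retained series.
#' The first `burn_in_gens` generations are discarded so the population is
#' at steady state.
#'
#' @param neutral_freqs Numeric vector: allele frequency at each successive
#'   generation.
#' @param burn_in_gens Number of leading generations to discard
#'   (default 100).
#' @return Estimated effective population size (scalar).
#' @examples
#' p <- wf_neutral_freqs(1000, 0.5, 500, seed = 1)
#' estimate_ne(p, burn_in_gens = 50)
#' @export
estimate_ne <- function(neutral_freqs, burn_in_gens = 100) {
  stopifnot(is.numeric(neutral_freqs))
  if (length(neutral_freqs) <= burn_in_gens + 2)
    stop("series too short for the requested burn-in")
  p <- neutral_freqs[-seq_len(burn_in_gens)]
  if (any(p <= 0 | p >= 1))
    stop("frequencies must lie strictly inside (0, 1) after burn-in")
  d2 <- diff(p)^2
  vbar <- mean(d2)
  if (vbar == 0) stop("no drift observed: effective size undefined")
  mean(head(p, -1) * (1 - head(p, -1))) / vbar
}

#' Neutral two-allele Wright-Fisher frequency path
#'
#' Binomial resampling of a biallelic neutral locus at constant size `N`;
#' the reference drift process for [estimate_ne()].
#'
#' @param N Population size.
#' @param p0 Initial frequency of allele 1.
#' @param n_gen Number of generations.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n_gen + 1` of allele-1 frequencies.
#' @export
wf_neutral_freqs <- function(N, p0, n_gen, seed = NULL) {
  stopifnot(N >= 1, p0 >= 0, p0 <= 1, n_gen >= 1)
  with_seed(seed)
  wf_neutral_core(N, p0, n_gen)
}

#' Neutral chemostat drift experiment
#'
#' Runs the stochastic chemostat with two selectively neutral lineages
#' started at equal frequency and no mutation, recording the frequency of
#' the first lineage at every generation after burn-in. Feeding the result
#' to [estimate_ne()] reproduces the effective-size calibration used to set
#' the Wright-Fisher population size.
#'
#' @param cparams A [chemostat_params()] object.
#' @param n_generations Number of generations to record (default 1000).
#' @param tau Leap length in hours.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n_generations + 1`: frequency of
#'   lineage 1 at generations `0..n_generations` (post burn-in clock).
#' @export
chemostat_neutral_freqs <- function(cparams = chemostat_params(),
                                    n_generations = 1000, tau = 0.1,
                                    seed = NULL) {
  ep <- evolution_params(0, 0, 0, 0)
  hours <- generation_to_hours(0:n_generations, cparams)
  st <- chemostat_run(cparams, ep, hours, tau = tau, init_frac_b = 0.5,
                      seed = seed)
  st$n_a / (st$n_a + st$n_b)
}
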