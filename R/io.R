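#' Fitness from a pairwise competition assay
#'
#' Estimates a per-generation selection coefficient from the frequencies of
#' a focal strain and a reference strain sampled over a competition
#' experiment: ordinary least squares of `ln(freq_focal / freq_ref)`
#' against elapsed hours, with the per-hour slope converted to
#' per-generation units by dividing by `ln 2` (the convention used with
#' these assays). A documented alternative converts via the culture's
#' generation time instead (`conversion = "generation_time"`, multiplying
#' the hourly slope by `generation_time_h`).
#'
#' In barcoded mode the assay is corrected for the marker cost: the
#' evolved-clone log-ratio series and a control series (unevolved barcoded
#' ancestor vs the same unlabeled reference) are fitted jointly with an
#' evolved-state interaction term, and the interaction slope is converted
#' identically.
#'
#' @param times_h Sampling times in hours (at least 3).
#' @param freq_focal,freq_ref Frequencies of the focal and reference
#'   strains, strictly inside (0, 1).
#' @param barcoded If `TRUE`, fit the interaction model; requires
#'   `control_focal`/`control_ref`.
#' @param control_focal,control_ref Control-pair frequencies on
#'   `control_times_h` (barcoded mode).
#' @param control_times_h Sampling times of the control series (defaults
#'   to `times_h`).
#' @param conversion `"ln2"` (default, divide the hourly slope by ln 2) or
#'   `"generation_time"` (multiply by `generation_time_h` hours per
#'   generation).
#' @param generation_time_h Generation time used by the alternative
#'   conversion (default 5.8 h).
#' @return A list with `s` (per generation), `ci` (95% confidence
#'   interval), `slope_per_h` and the fitted `model`.
#' @examples
#' t <- seq(0, 21, by = 3)
#' lr <- 0.05 * t - 2
#' f <- exp(lr) / (1 + exp(lr))
#' competition_fitness(t, f, 1 - f)$s  # 0.05 / ln 2
#' @export
competition_fitness <- function(times_h, freq_focal, freq_ref,
                                barcoded = FALSE, control_focal = NULL,
                                control_ref = NULL,
                                control_times_h = times_h,
                                conversion = c("ln2", "generation_time"),
                                generation_time_h = 5.8) {
  conversion <- match.arg(conversion)
  check_comp <- function(t, f, r) {
    if (length(t) < 3) stop("need at least 3 time points")
    if (length(f) != length(t) || length(r) != length(t))
      stop("frequency series must match the time points")
    if (any(f <= 0 | f >= 1 | r <= 0 | r >= 1))
      stop("frequencies must lie strictly inside (0, 1)")
  }
  check_comp(times_h, freq_focal, freq_ref)
  conv <- function(slope) {
    if (conversion == "ln2") slope / log(2) else slope * generation_time_h
  }
  if (!barcoded) {
    df <- data.frame(lr = log(freq_focal / freq_ref), hours = times_h)
    fit <- lm(lr ~ hours, data = df)
    ci <- confint(fit)["hours", ]
    return(list(s = conv(unname(coef(fit)["hours"])),
                ci = conv(unname(ci)),
                slope_per_h = unname(coef(fit)["hours"]), model = fit))
  }
  if (is.null(control_focal) || is.null(control_ref))
    stop("barcoded mode requires the control frequency series")
  check_comp(control_times_h, control_focal, control_ref)
  df <- rbind(data.frame(lr = log(freq_focal / freq_ref), hours = times_h,
                         evolved = 1),
              data.frame(lr = log(control_focal / control_ref),
                         hours = control_times_h, evolved = 0))
  fit <- lm(lr ~ hours * evolved, data = df)
  ci <- confint(fit)["hours:evolved", ]
  list(s = conv(unname(coef(fit)["hours:evolved"])), ci = conv(unname(ci)),
       slope_per_h = unname(coef(fit)["hours:evolved"]), model = fit)
}

#' Run configuration
#'
#' Bundles and validates the knobs of an inference run: the evolutionary
#' model, inference method, prior bounds, simulation budget, seed, data
#' truncation generation and simulator settings. Defaults are the study
#' conditions: priors `[1e-12, 1e-3]` and `[1e-4, 0.4]`, nuisance
#' parameters `delta_b = 1e-5`, `s_b = 0.001`, truncation at generation
#' 116, tau-leap step 0.1 h and the standard chemostat constants.
#'
#' @param model `"wf"` or `"chemo"`.
#' @param method `"npe"` or `"abc_smc"`.
#' @param prior A [prior_spec()].
#' @param budget Simulation/particle budget.
#' @param seed Integer seed.
#' @param truncate_gen Maximum generation used for inference (default
#'   116); `Inf` disables truncation.
#' @param delta_b,s_b Other-beneficial nuisance parameters.
#' @param tau Tau-leap step (h).
#' @param n_pop Wright-Fisher population size.
#' @param cparams [chemostat_params()].
#' @param out Optional output path.
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(model = "wf", method = "npe", prior = prior_spec(),
                       budget = 10000, seed = 1, truncate_gen = 116,
                       delta_b = 1e-5, s_b = 0.001, tau = 0.1,
                       n_pop = 3.3e8, cparams = chemostat_params(),
                       out = NULL) {
  if (!model %in% c("wf", "chemo")) stop("unknown model: ", model)
  if (!method %in% c("npe", "abc_smc")) stop("unknown method: ", method)
  stopifnot(inherits(prior, "prior_spec"), budget >= 100,
            truncate_gen > 0, tau > 0, n_pop >= 1,
            inherits(cparams, "chemostat_params"))
  structure(list(model = model, method = method, prior = prior,
                 budget = budget, seed = as.integer(seed),
                 truncate_gen = truncate_gen, delta_b = delta_b,
                 s_b = s_b, tau = tau, n_pop = n_pop, cparams = cparams,
                 out = out),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$prior <- unclass(x$prior)
  x$cparams <- unclass(x$cparams)
  if (is.infinite(x$truncate_gen)) x$truncate_gen <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pr <- structure(list(lower = as.numeric(x$prior$lower),
                       upper = as.numeric(x$prior$upper),
                       names = as.character(x$prior$names)),
                  class = "prior_spec")
  cp <- do.call(chemostat_params, x$cparams)
  run_config(model = x$model, method = x$method, prior = pr,
             budget = x$budget, seed = x$seed,
             truncate_gen = if (is.null(x$truncate_gen)) Inf
                            else x$truncate_gen,
             delta_b = x$delta_b, s_b = x$s_b, tau = x$tau,
             n_pop = x$n_pop, cparams = cp,
             out = x$out)
}
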