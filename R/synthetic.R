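#' Benchmark suite over a parameter grid
#'
#' Generates the standard benchmark design: `n_rep` synthetic observations
#' per combination of simulator and `(delta_c, s_c)` values, each tagged
#' with its generating model, true parameters and child seed. The default
#' grid (2 models x 2 formation rates x 2 selection coefficients x 5
#' replicates) yields 40 observations.
#'
#' @param models Character subset of `c("wf", "chemo")`.
#' @param deltas Focal formation rates (default `c(1e-5, 1e-7)`).
#' @param esses Focal selection coefficients (default `c(0.001, 0.1)`).
#' @param n_rep Replicates per combination (default 5).
#' @param seed Integer seed; the whole suite is reproducible from it.
#' @param sample_times Common generation grid.
#' @param N Wright-Fisher population size.
#' @param cparams [chemostat_params()] for chemostat observations.
#' @return An object of class `"cnv_suite"`: a list with `design` (data
#'   frame) and `observations` (list of records with `trajectory`,
#'   `model`, `delta_c`, `s_c`, `seed`).
#' @export
make_grid_suite <- function(models = c("wf", "chemo"),
                            deltas = c(1e-5, 1e-7),
                            esses = c(0.001, 0.1), n_rep = 5, seed = 1,
                            sample_times = default_grid(), N = 3.3e8,
                            cparams = chemostat_params()) {
  stopifnot(length(models) >= 1, length(deltas) >= 1, length(esses) >= 1,
            n_rep >= 1)
  models <- match.arg(models, c("wf", "chemo"), several.ok = TRUE)
  design <- expand.grid(model = models, delta_c = deltas, s_c = esses,
                        rep = seq_len(n_rep), stringsAsFactors = FALSE)
  handles <- list()
  for (m in models)
    handles[[m]] <- cnv_model(m, sample_times = sample_times, N = N,
                              cparams = cparams)
  observations <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    sd_i <- child_seed(seed, i)
    tr <- handles[[design$model[i]]]$simulate(design$delta_c[i],
                                              design$s_c[i], seed = sd_i)
    observations[[i]] <- list(trajectory = tr, model = design$model[i],
                              delta_c = design$delta_c[i],
                              s_c = design$s_c[i], seed = sd_i)
  }
  structure(list(design = design, observations = observations,
                 seed = seed, sample_times = sample_times),
            class = "cnv_suite")
}

#' @export
print.cnv_suite <- function(x, ...) {
  cat(sprintf("Benchmark suite: %d observations\n",
              length(x$observations)))
  print(utils::head(x$design, 8))
  invisible(x)
}

#' Observation set with Gamma-distributed selection coefficients
#'
#' Draws `n_obs` selection coefficients from a Gamma DFE and simulates one
#' Wright-Fisher observation per draw (all sharing `delta_c`). Draws
#' falling outside the single-observation prior support for `s_c`
#' (`1e-4` to `0.4`) are clipped to it with a warning. Each record stores
#' the drawn coefficient as its truth.
#'
#' @param dfe A [gamma_dfe()].
#' @param delta_c Shared focal formation rate.
#' @param n_obs Number of observations (default 11).
#' @param seed Integer seed.
#' @param model Optional [cnv_model()] to simulate with (defaults to a
#'   Wright-Fisher handle on the default grid).
#' @return A `"cnv_suite"` whose records carry per-observation `s_c`.
#' @export
make_dfe_suite <- function(dfe, delta_c, n_obs = 11, seed = 1,
                           model = NULL) {
  stopifnot(inherits(dfe, "gamma_dfe"))
  if (is.null(model)) model <- cnv_model("wf")
  s <- sample_dfe(dfe, n_obs, seed = seed)
  if (any(s < 1e-4 | s > 0.4)) {
    warning("selection coefficients outside prior support [1e-4, 0.4] ",
            "were clipped")
    s <- pmin(pmax(s, 1e-4), 0.4)
  }
  observations <- vector("list", n_obs)
  for (i in seq_len(n_obs)) {
    sd_i <- child_seed(seed, i)
    tr <- model$simulate(delta_c, s[i], seed = sd_i)
    observations[[i]] <- list(trajectory = tr, model = model$model,
                              delta_c = delta_c, s_c = s[i], seed = sd_i)
  }
  structure(list(design = data.frame(model = model$model,
                                     delta_c = delta_c, s_c = s,
                                     rep = seq_len(n_obs)),
                 observations = observations, seed = seed,
                 sample_times = model$grid, dfe = dfe),
            class = "cnv_suite")
}

#' Pseudo-empirical CSV bundle
#'
#' Emulates the layout of the empirical dataset: 11 replicate populations
#' (`gln_01` to `gln_09`, `bc01`, `bc02`) sampled at 25 time points to
#' generation 267, written as trajectory CSVs with one truth sidecar JSON
#' per population (`<name>.truth.json`, holding the generating model, true
#' parameters and seed; the trajectory CSV itself stays truth-free). The
#' populations share a formation rate of `10^-4.3` and draw their
#' selection coefficients from a `Gamma(10, 0.007)` DFE (mean 0.07),
#' emulating the spread of the empirical replicates; this is synthetic
#' data, not a copy of the deposited trajectories.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param delta_c Shared formation rate (default `10^-4.3`).
#' @param dfe DFE for the per-population selection coefficients.
#' @return Invisibly, a data frame with columns `name`, `csv`, `truth`.
#' @export
make_pseudo_empirical_bundle <- function(dir, seed = 1,
                                         delta_c = 10^-4.3,
                                         dfe = gamma_dfe(10, 0.007)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  names <- c(sprintf("gln_%02d", 1:9), "bc01", "bc02")
  suite <- make_dfe_suite(dfe, delta_c, n_obs = length(names), seed = seed)
  files <- data.frame(name = names, csv = NA_character_,
                      truth = NA_character_)
  for (i in seq_along(names)) {
    rec <- suite$observations[[i]]
    csv <- file.path(dir, paste0(names[i], ".csv"))
    truth <- file.path(dir, paste0(names[i], ".truth.json"))
    write_trajectory(rec$trajectory, csv)
    jsonlite::write_json(list(model = rec$model, delta_c = rec$delta_c,
                              s_c = rec$s_c, seed = rec$seed),
                         truth, auto_unbox = TRUE, digits = NA)
    files$csv[i] <- csv
    files$truth[i] <- truth
  }
  invisible(files)
}
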