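#' Construct a trajectory of focal-mutant proportion
#'
#' The universal observation format: the proportion of the population
#' carrying the focal CNV, sampled on a grid of generations.
#'
#' @param generations Strictly increasing numeric vector of sample times
#'   (generations, >= 0).
#' @param proportions Numeric vector in `[0, 1]`, same length.
#'
#' @return A data frame of class `"cnv_trajectory"` with columns
#'   `generation` and `proportion`.
#' @examples
#' trajectory(c(0, 50, 100), c(0, 0.2, 0.9))
#' @export
trajectory <- function(generations, proportions) {
  if (length(generations) == 0) stop("trajectory must have at least one point")
  if (length(generations) != length(proportions))
    stop("generations and proportions must have equal length")
  if (any(!is.finite(generations)) || any(!is.finite(proportions)))
    stop("trajectory values must be finite")
  if (any(generations < 0)) stop("generations must be non-negative")
  if (any(diff(generations) <= 0))
    stop("generations must be strictly increasing")
  if (any(proportions < 0 | proportions > 1))
    stop("proportions must lie in [0, 1]")
  structure(data.frame(generation = as.numeric(generations),
                       proportion = as.numeric(proportions)),
            class = c("cnv_trajectory", "data.frame"))
}

#' Default sampling grid
#'
#' 25 evenly spaced time points from generation 0 to 267, mirroring the
#' layout of the empirical evolution experiments.
#'
#' @param n_timepoints Number of sample times.
#' @param max_generation Final generation.
#' @return Numeric vector of generations.
#' @export
default_grid <- function(n_timepoints = 25, max_generation = 267) {
  stopifnot(n_timepoints >= 2, max_generation > 0)
  seq(0, max_generation, length.out = n_timepoints)
}

#' @export
print.cnv_trajectory <- function(x, ...) {
  cat(sprintf("CNV proportion trajectory: %d time points, generations %g-%g\n",
              nrow(x), min(x$generation), max(x$generation)))
  cat(sprintf("  final proportion: %.4g\n", x$proportion[nrow(x)]))
  invisible(x)
}

#' @export
plot.cnv_trajectory <- function(x, ..., type = "b", ylim = c(0, 1),
                                xlab = "Generation",
                                ylab = "Proportion with CNV") {
  graphics::plot(x$generation, x$proportion, type = type, ylim = ylim,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Read / write a trajectory CSV
#'
#' The on-disk format is a UTF-8 CSV with header `generation,proportion`,
#' one row per sample time, `.` as the decimal mark. Malformed files are
#' rejected with the offending row named.
#'
#' @param path File path.
#' @return `read_trajectory()` returns a [trajectory()] object;
#'   `write_trajectory()` returns `path` invisibly.
#' @examples
#' tr <- trajectory(c(0, 10), c(0, 0.5))
#' f <- tempfile(fileext = ".csv")
#' write_trajectory(tr, f)
#' identical(read_trajectory(f)$proportion, tr$proportion)
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse CSV: ",
                                          conditionMessage(e)))
  if (nrow(df) == 0) stop("empty trajectory file: ", path)
  if (!all(c("generation", "proportion") %in% names(df)))
    stop("missing required header 'generation,proportion' in ", path)
  gen <- suppressWarnings(as.numeric(df$generation))
  pro <- suppressWarnings(as.numeric(df$proportion))
  bad <- which(!is.finite(gen) | !is.finite(pro))
  if (length(bad))
    stop("non-numeric values at row(s) ", paste(bad, collapse = ", "))
  bad <- which(pro < 0 | pro > 1)
  if (length(bad))
    stop("proportion outside [0, 1] at row(s) ", paste(bad, collapse = ", "))
  if (any(diff(gen) <= 0))
    stop("generations not strictly increasing at row ",
         which(diff(gen) <= 0)[1] + 1)
  trajectory(gen, pro)
}

#' @param traj A [trajectory()] object.
#' @rdname read_trajectory
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "cnv_trajectory"))
  write.csv(data.frame(generation = traj$generation,
                       proportion = traj$proportion),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Interpolate a trajectory onto a new generation grid
#'
#' Linear interpolation between the two nearest (bracketing) time points;
#' target generations already present in the source grid keep their exact
#' values. Extrapolation outside the observed range is an error.
#'
#' @param traj A [trajectory()].
#' @param target Numeric vector of generations within the observed range.
#' @return A [trajectory()] on `target`.
#' @export
interpolate_to_grid <- function(traj, target) {
  stopifnot(inherits(traj, "cnv_trajectory"))
  if (any(target < min(traj$generation) - 1e-9) ||
      any(target > max(traj$generation) + 1e-9))
    stop("target grid requires extrapolation outside the observed range")
  out <- approx(traj$generation, traj$proportion, xout = target,
                method = "linear", ties = "ordered")$y
  trajectory(target, pmin(1, pmax(0, out)))
}

#' Truncate a trajectory at a maximum generation
#'
#' Keeps the sample times with `generation <= max_gen`. Used to restrict
#' inference to the early, monotone phase of the dynamics (the empirical
#' analysis truncates at generation 116).
#'
#' @param traj A [trajectory()].
#' @param max_gen Maximum generation to keep (default 116).
#' @return A [trajectory()].
#' @export
truncate_trajectory <- function(traj, max_gen = 116) {
  stopifnot(inherits(traj, "cnv_trajectory"))
  if (max_gen < traj$generation[1])
    stop("max_gen precedes the first sample time; nothing would remain")
  keep <- traj$generation <= max_gen
  trajectory(traj$generation[keep], traj$proportion[keep])
}
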