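# Internal constructor for the common posterior container produced by both
# inference engines. `samples` live in the working (log10 where applicable)
# parameterization; `transform` records how to map back to natural scale.
new_posterior <- function(samples, weights = NULL, log_density = NULL,
                          sampler = NULL, prior, method,
                          diagnostics = list()) {
  samples <- rbind(samples)
  n <- nrow(samples)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (any(weights < 0)) stop("weights must be non-negative")
  weights <- weights / sum(weights)
  colnames(samples) <- prior$names
  structure(list(samples = samples, weights = weights,
                 log_density = log_density, sampler = sampler,
                 prior = prior, method = method,
                 diagnostics = diagnostics),
            class = "cnv_posterior")
}

# Map a working-space matrix to natural scale using the parameter names:
# any column named log10_* is exponentiated and loses the prefix.
to_natural <- function(theta, names) {
  theta <- rbind(theta)
  out <- theta
  nm <- names
  for (j in seq_along(nm)) {
    if (startsWith(nm[j], "log10_")) {
      out[, j] <- 10^theta[, j]
      nm[j] <- sub("^log10_", "", nm[j])
    }
  }
  colnames(out) <- nm
  out
}

from_natural <- function(theta_nat, names) {
  theta_nat <- rbind(theta_nat)
  out <- theta_nat
  for (j in seq_along(names)) {
    if (startsWith(names[j], "log10_")) out[, j] <- log10(theta_nat[, j])
  }
  colnames(out) <- names
  out
}

#' @export
print.cnv_posterior <- function(x, ...) {
  cat(sprintf("Posterior (%s): %d weighted samples over (%s)\n",
              x$method, nrow(x$samples), paste(x$prior$names,
                                               collapse = ", ")))
  if (!is.null(x$diagnostics$ess))
    cat(sprintf("  final ESS: %.1f\n", tail(x$diagnostics$ess, 1)))
  invisible(x)
}

#' @export
summary.cnv_posterior <- function(object, ...) {
  qs <- apply(object$samples, 2, function(v)
    weighted_quantile(v, object$weights, c(0.025, 0.5, 0.975)))
  map <- map_estimate(object, natural = FALSE)
  out <- list(quantiles = qs, map = map,
              ess = 1 / sum(object$weights^2), method = object$method)
  class(out) <- "summary.cnv_posterior"
  out
}

#' @export
print.summary.cnv_posterior <- function(x, ...) {
  cat(sprintf("Posterior summary (%s), ESS %.1f\n", x$method, x$ess))
  cat("MAP (working scale):\n")
  print(x$map)
  cat("2.5/50/97.5% weighted quantiles:\n")
  print(x$quantiles)
  invisible(x)
}

#' @export
plot.cnv_posterior <- function(x, ...) {
  s <- x$samples
  if (ncol(s) < 2) {
    graphics::hist(s[, 1], breaks = 40, main = "Posterior",
                   xlab = colnames(s)[1], ...)
  } else {
    cex <- 0.3 + 2 * x$weights / max(x$weights)
    graphics::plot(s[, 1], s[, 2], pch = 16,
                   col = grDevices::adjustcolor("steelblue", 0.4),
                   cex = cex, xlab = colnames(s)[1],
                   ylab = colnames(s)[2], ...)
  }
  invisible(x)
}

#' Draw samples from a posterior
#'
#' Uses the posterior's exact sampler when available (amortized neural
#' posteriors), otherwise resamples the weighted particle set.
#'
#' @param post A `cnv_posterior`.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return An `n x d` matrix in the working (log10) parameterization.
#' @export
posterior_sample <- function(post, n, seed = NULL) {
  stopifnot(inherits(post, "cnv_posterior"))
  with_seed(seed)
  if (!is.null(post$sampler)) return(post$sampler(n))
  idx <- sample.int(nrow(post$samples), n, replace = TRUE,
                    prob = post$weights)
  post$samples[idx, , drop = FALSE]
}

# Weighted quantiles (type-4-like, linear on the weighted ECDF).
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  approx(cw, x, xout = probs, rule = 2, ties = "ordered")$y
}

# ---- weighted Gaussian KDE --------------------------------------------------

# Silverman's rule per dimension on weighted samples (effective sample size
# in place of n).
silverman_bw <- function(samples, weights) {
  n_eff <- 1 / sum(weights^2)
  d <- ncol(samples)
  sds <- sapply(seq_len(d), function(j) {
    m <- weighted.mean(samples[, j], weights)
    sqrt(max(weighted.mean((samples[, j] - m)^2, weights), 1e-20))
  })
  sds * (4 / (d + 2))^(1 / (d + 4)) * n_eff^(-1 / (d + 4))
}

# Log-density of the weighted product-Gaussian KDE at rows of `at`.
kde_logdensity <- function(at, samples, weights, bw = NULL) {
  at <- rbind(at)
  if (is.null(bw)) bw <- silverman_bw(samples, weights)
  bw <- pmax(bw, 1e-12)
  logw <- log(weights)
  apply(at, 1, function(p) {
    lk <- logw
    for (j in seq_len(ncol(samples)))
      lk <- lk + dnorm(p[j], samples[, j], bw[j], log = TRUE)
    m <- max(lk)
    m + log(sum(exp(lk - m)))
  })
}

# Posterior log-density in working space: exact when the estimator provides
# one, otherwise the weighted KDE over the particle set.
posterior_logdensity_fn <- function(post) {
  if (!is.null(post$log_density)) return(post$log_density)
  bw <- silverman_bw(post$samples, post$weights)
  function(theta) kde_logdensity(theta, post$samples, post$weights, bw)
}

# ---- MAP, HDI, HDR ----------------------------------------------------------

#' Maximum a posteriori estimate
#'
#' The mode of the posterior density in the working (log10) space, found by
#' Nelder-Mead simplex searches restarted from the highest-density posterior
#' samples, then mapped back to natural scale. For particle posteriors the
#' density is a weighted Gaussian kernel density estimate (Silverman
#' bandwidth); amortized neural posteriors are maximized exactly.
#'
#' @param post A `cnv_posterior` (at least 1000 samples recommended for
#'   KDE-based estimates).
#' @param natural If `TRUE` (default) return on natural scale (e.g.
#'   `delta_c`, `s_c`); otherwise the working scale.
#' @param n_starts Number of simplex restarts (from the `n_starts`
#'   highest-density samples).
#' @return Named numeric vector.
#' @export
map_estimate <- function(post, natural = TRUE, n_starts = 5) {
  stopifnot(inherits(post, "cnv_posterior"))
  s <- post$samples
  if (nrow(s) == 1 || all(apply(s, 2, function(v) diff(range(v)) == 0))) {
    best <- s[1, ]
  } else {
    f <- posterior_logdensity_fn(post)
    dens_at_samples <- f(s)
    ord <- order(dens_at_samples, decreasing = TRUE)
    starts <- s[head(ord, n_starts), , drop = FALSE]
    lo <- post$prior$lower; hi <- post$prior$upper
    neg <- function(th) {
      th <- pmin(pmax(th, lo), hi)
      -f(rbind(th))
    }
    best <- NULL; bestv <- Inf
    for (i in seq_len(nrow(starts))) {
      o <- tryCatch(optim(starts[i, ], neg, method = "Nelder-Mead",
                          control = list(maxit = 500)),
                    error = function(e) NULL)
      if (!is.null(o) && o$value < bestv) {
        bestv <- o$value
        best <- pmin(pmax(o$par, lo), hi)
      }
    }
    if (is.null(best)) stop("MAP optimization failed to converge")
  }
  names(best) <- post$prior$names
  if (natural) drop(to_natural(rbind(best), post$prior$names)) else best
}

#' Highest density interval of a posterior marginal
#'
#' Shortest interval containing `level` posterior mass of the weighted
#' marginal sample for one parameter.
#'
#' @param post A `cnv_posterior`, or a numeric sample vector.
#' @param par Column index or name of the parameter (ignored for vectors).
#' @param level Credibility level in (0, 1), default 0.95.
#' @param weights Optional weights when `post` is a numeric vector.
#' @return Length-2 numeric `c(lower, upper)` on the working scale.
#' @export
hdi <- function(post, par = 1, level = 0.95, weights = NULL) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (inherits(post, "cnv_posterior")) {
    x <- post$samples[, par]
    w <- post$weights
  } else {
    x <- as.numeric(post)
    w <- if (is.null(weights)) rep(1 / length(x), length(x)) else weights
  }
  if (length(x) < 2 || diff(range(x)) == 0) return(c(x[1], x[1]))
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  n <- length(x)
  best <- c(x[1], x[n]); bestw <- Inf
  j <- 1
  for (i in seq_len(n)) {
    lowmass <- if (i > 1) cw[i - 1] else 0
    if (j < i) j <- i
    while (j <= n && cw[j] - lowmass < level) j <- j + 1
    if (j > n) break
    if (x[j] - x[i] < bestw) {
      bestw <- x[j] - x[i]
      best <- c(x[i], x[j])
    }
  }
  best
}

#' Joint highest-density-region membership
#'
#' Tests whether a supplied true parameter pair falls inside the `level`
#' highest density region of the posterior: the density at the truth must
#' reach the density threshold below which the lowest-density `1 - level`
#' posterior mass falls (empirical HDR via the density quantile at the
#' posterior samples).
#'
#' @param post A `cnv_posterior`.
#' @param truth Named natural-scale vector (e.g. `c(delta_c = 1e-5,
#'   s_c = 0.1)`) or working-scale if `natural = FALSE`.
#' @param level HDR level (e.g. 0.5 or 0.95).
#' @param natural Whether `truth` is on natural scale (default `TRUE`).
#' @return Logical scalar.
#' @export
hdr_contains <- function(post, truth, level = 0.95, natural = TRUE) {
  stopifnot(inherits(post, "cnv_posterior"))
  th <- if (natural) from_natural(rbind(truth), post$prior$names)
        else rbind(truth)
  f <- posterior_logdensity_fn(post)
  dens_samples <- f(post$samples)
  thr <- weighted_quantile(dens_samples, post$weights, 1 - level)
  as.logical(f(th) >= thr)
}

#' Log ratio of an estimate to the truth
#'
#' `log10(estimate / truth)`; zero for a perfect estimate, 1 for a 10-fold
#' overestimate.
#'
#' @param estimate,truth Positive scalars (or equal-length vectors).
#' @return Numeric.
#' @export
log_ratio <- function(estimate, truth) {
  if (any(estimate <= 0) || any(truth <= 0))
    stop("log ratio requires positive values")
  log10(estimate / truth)
}

# ---- posterior predictive checks and information criteria -------------------

#' Posterior predictive check
#'
#' Simulates one trajectory per parameter draw from the posterior (plus one
#' at the MAP) with the generating model, and scores each against the
#' observation by root-mean-square error and Pearson correlation across
#' time points. Correlation against a constant trajectory is reported as
#' `NA`, not zero.
#'
#' @param post A `cnv_posterior` over `(log10_delta_c, log10_s_c)`.
#' @param model A [cnv_model()] simulator handle on the observation's grid.
#' @param observed A [trajectory()].
#' @param n_draws Number of posterior draws (default 50).
#' @param seed Optional integer seed.
#' @return A list with per-draw `rmse` and `corr`, `map_rmse`, `map_corr`,
#'   and `summary` (mean and normal-theory 95% CI of each measure).
#' @export
posterior_predict <- function(post, model, observed, n_draws = 50,
                              seed = NULL) {
  stopifnot(inherits(post, "cnv_posterior"), inherits(model, "cnv_model"),
            inherits(observed, "cnv_trajectory"))
  if (!isTRUE(all.equal(model$grid, observed$generation)))
    stop("observation grid does not match the model's sample grid")
  with_seed(seed)
  draws <- posterior_sample(post, n_draws)
  obs <- observed$proportion
  score <- function(theta_work) {
    nat <- drop(to_natural(rbind(theta_work), post$prior$names))
    sim <- model$simulate_vec(c(log10(nat[["delta_c"]]),
                                log10(nat[["s_c"]])))
    rmse <- sqrt(mean((sim - obs)^2))
    corr <- if (sd(sim) == 0 || sd(obs) == 0) NA_real_ else cor(sim, obs)
    c(rmse = rmse, corr = corr)
  }
  per_draw <- t(apply(draws, 1, score))
  map_w <- map_estimate(post, natural = FALSE)
  map_sc <- score(map_w)
  ci <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(c(mean = NA, lo = NA, hi = NA))
    se <- sd(v) / sqrt(length(v))
    c(mean = mean(v), lo = mean(v) - 1.96 * se, hi = mean(v) + 1.96 * se)
  }
  list(rmse = per_draw[, "rmse"], corr = per_draw[, "corr"],
       map_rmse = unname(map_sc["rmse"]), map_corr = unname(map_sc["corr"]),
       summary = rbind(rmse = ci(per_draw[, "rmse"]),
                       corr = ci(per_draw[, "corr"])))
}

# Gaussian surrogate likelihood: repeated simulation at theta gives a
# per-time-point normal model for the observation. sd_floor guards time
# points where all replicates agree (e.g. the all-zero early points);
# 1e-3 corresponds to roughly the resolution of proportion measurements.
surrogate_loglik <- function(theta_work, model, obs, names, n_rep = 100,
                             sd_floor = 1e-3) {
  nat <- drop(to_natural(rbind(theta_work), names))
  sims <- replicate(n_rep, model$simulate_vec(c(log10(nat[["delta_c"]]),
                                                log10(nat[["s_c"]]))))
  m <- rowMeans(sims)
  s <- pmax(apply(sims, 1, sd), sd_floor)
  dnorm(obs, m, s, log = TRUE)  # pointwise log-likelihood, one per time point
}

#' Information criteria for a fitted posterior
#'
#' AIC at the MAP (`-2 log p(y|theta_hat) + 2k`, `k = 2`) and the two
#' common WAIC formulas over posterior draws, computed with a surrogate
#' likelihood: because the simulators admit no tractable likelihood, the
#' pointwise density `p(y_t | theta)` is taken as Gaussian with mean and
#' standard deviation estimated from `n_rep` repeat simulations at `theta`.
#' WAIC1 penalizes by `2 sum_t (log E_s p - E_s log p)`; WAIC2 by
#' `2 sum_t Var_s(log p)`. Lower values indicate better expected predictive
#' accuracy; differences of 2 or more are conventionally meaningful.
#'
#' @param post A `cnv_posterior` over `(log10_delta_c, log10_s_c)`.
#' @param model A [cnv_model()] on the observation's grid.
#' @param observed A [trajectory()].
#' @param n_draws Posterior draws `S` for WAIC (default 50).
#' @param n_rep Repeat simulations per draw for the surrogate (default 100).
#' @param sd_floor Lower bound on the surrogate standard deviation.
#' @param seed Optional integer seed.
#' @return Named numeric: `aic`, `waic1`, `waic2`.
#' @export
information_criteria <- function(post, model, observed, n_draws = 50,
                                 n_rep = 100, sd_floor = 1e-3, seed = NULL) {
  stopifnot(inherits(post, "cnv_posterior"), inherits(model, "cnv_model"))
  with_seed(seed)
  obs <- observed$proportion
  map_w <- map_estimate(post, natural = FALSE)
  ll_map <- surrogate_loglik(map_w, model, obs, post$prior$names, n_rep,
                             sd_floor)
  aic <- -2 * sum(ll_map) + 2 * 2
  draws <- posterior_sample(post, n_draws)
  # n_time x S matrix of pointwise log-likelihoods
  ll <- sapply(seq_len(nrow(draws)), function(s)
    surrogate_loglik(draws[s, ], model, obs, post$prior$names, n_rep,
                     sd_floor))
  crit <- waic_from_loglik(ll)
  c(aic = aic, waic1 = unname(crit["waic1"]),
    waic2 = unname(crit["waic2"]))
}

# WAIC from an n_obs x S pointwise log-likelihood matrix; both standard
# formulations. Kept free of posterior/model objects so it can be checked
# directly against an independent transcription.
waic_from_loglik <- function(ll) {
  ll <- rbind(ll)
  S <- ncol(ll)
  # log (1/S) sum_s p, computed stably
  lppd_i <- apply(ll, 1, function(v) {
    m <- max(v)
    m + log(mean(exp(v - m)))
  })
  p1_i <- lppd_i - rowMeans(ll)
  p2_i <- apply(ll, 1, var)
  c(waic1 = -2 * sum(lppd_i) + 2 * sum(p1_i),
    waic2 = -2 * sum(lppd_i) + 2 * sum(p2_i))
}
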