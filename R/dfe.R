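#' Gamma distribution of fitness effects
#'
#' Shape/scale parameterization: `s ~ Gamma(alpha, beta)` with expected
#' value `alpha * beta`.
#'
#' @param alpha Shape (> 0), dimensionless.
#' @param beta Scale (> 0), per-generation units.
#' @return An object of class `"gamma_dfe"`.
#' @examples
#' gamma_dfe(1, 0.1)       # exponential DFE with mean 0.1
#' gamma_dfe(10, 0.01)     # sum of 10 exponentials, mean 0.1
#' @export
gamma_dfe <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), is.numeric(beta))
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  structure(list(alpha = alpha, beta = beta), class = "gamma_dfe")
}

#' @export
print.gamma_dfe <- function(x, ...) {
  cat(sprintf("Gamma DFE: shape %.4g, scale %.4g (mean s = %.4g)\n",
              x$alpha, x$beta, x$alpha * x$beta))
  invisible(x)
}

#' Sample selection coefficients from a DFE
#'
#' @param dfe A [gamma_dfe()].
#' @param n Number of draws (the study samples 11, one per replicate
#'   population).
#' @param seed Optional integer seed.
#' @return Numeric vector of positive selection coefficients.
#' @export
sample_dfe <- function(dfe, n = 11, seed = NULL) {
  stopifnot(inherits(dfe, "gamma_dfe"), n >= 1)
  with_seed(seed)
  rgamma(n, shape = dfe$alpha, scale = dfe$beta)
}

#' Maximum-likelihood Gamma fit
#'
#' Fits shape and scale by maximum likelihood (method-of-moments starting
#' values). Degenerate inputs (all values equal) are rejected.
#'
#' @param s_values At least 3 positive selection coefficients.
#' @return A [gamma_dfe()].
#' @export
fit_gamma <- function(s_values) {
  s_values <- as.numeric(s_values)
  if (length(s_values) < 3) stop("need at least 3 values")
  if (any(s_values <= 0)) stop("values must be positive")
  if (diff(range(s_values)) == 0)
    stop("degenerate input: all values equal; Gamma fit undefined")
  m <- mean(s_values); v <- var(s_values)
  start <- list(shape = m^2 / v, rate = m / v)
  fit <- MASS::fitdistr(s_values, "gamma", start = start,
                        lower = c(1e-8, 1e-8))
  gamma_dfe(unname(fit$estimate["shape"]),
            1 / unname(fit$estimate["rate"]))
}

#' Kullback-Leibler divergence between Gamma distributions
#'
#' Closed form for shape/scale Gammas:
#' `KL(p || q) = (a_p - a_q) digamma(a_p) - log Gamma(a_p) +
#' log Gamma(a_q) + a_q (log b_q - log b_p) + a_p (b_p - b_q) / b_q`.
#' Non-negative, zero iff the distributions coincide.
#'
#' @param p,q [gamma_dfe()] objects (`p` the reference, `q` the
#'   approximation: the package convention is `kl_gamma(inferred, true)`
#'   reported as KL(inferred || true)).
#' @return Non-negative scalar.
#' @export
kl_gamma <- function(p, q) {
  stopifnot(inherits(p, "gamma_dfe"), inherits(q, "gamma_dfe"))
  (p$alpha - q$alpha) * digamma(p$alpha) - lgamma(p$alpha) +
    lgamma(q$alpha) + q$alpha * (log(q$beta) - log(p$beta)) +
    p$alpha * (p$beta - q$beta) / q$beta
}

#' Compare the two DFE-recovery strategies
#'
#' Generates a set of `n_obs` Wright-Fisher observations whose selection
#' coefficients are drawn from a known Gamma DFE, then recovers the DFE two
#' ways using three different subsets of 8 observations (the held-out
#' triples are as disjoint as possible):
#'
#' * Strategy A ("single-observation"): infer `(delta_c, s_c)` separately
#'   for each of the 8 observations with the amortized single-observation
#'   estimator, take the MAP selection coefficients, and fit a Gamma
#'   distribution to them.
#' * Strategy B ("observation-set"): condition the amortized set estimator
#'   on the 8 observations jointly and take the MAP `(alpha, beta)`.
#'
#' Each recovered DFE is scored by `KL(inferred || true)`; strategy B is
#' additionally scored by out-of-sample posterior predictive RMSE on the 3
#' held-out observations.
#'
#' @param true_dfe A [gamma_dfe()].
#' @param delta_c True focal formation rate used for all observations.
#' @param npe_single A [fit_npe()] amortized estimator (Wright-Fisher).
#' @param npe_set A [fit_npe_set()] amortized set estimator.
#' @param model The [cnv_model()] used to generate observations and
#'   posterior predictions (its grid must match the estimators').
#' @param n_obs Observations in the set (default 11).
#' @param n_ppc Posterior predictive draws per held-out observation.
#' @param seed Integer seed.
#' @return A list with elements `kl_single`, `kl_set` (length-3 vectors,
#'   one per subset), `ppc_rmse_set` (mean held-out RMSE per subset),
#'   `fits_single`, `fits_set` (the recovered [gamma_dfe()]s), `s_true`
#'   and the subset definitions.
#' @export
compare_dfe_strategies <- function(true_dfe, delta_c, npe_single, npe_set,
                                   model, n_obs = 11, n_ppc = 20,
                                   seed = NULL) {
  stopifnot(inherits(true_dfe, "gamma_dfe"))
  with_seed(seed)
  suite <- make_dfe_suite(true_dfe, delta_c, n_obs = n_obs,
                          seed = child_seed(if (is.null(seed)) 0 else seed,
                                            1),
                          model = model)
  obs <- lapply(suite$observations, `[[`, "trajectory")
  s_true <- sapply(suite$observations, `[[`, "s_c")
  n_fit <- npe_set$n_obs
  n_hold <- n_obs - n_fit
  holdouts <- lapply(seq_len(3), function(r)
    ((r - 1) * n_hold + seq_len(n_hold) - 1) %% n_obs + 1)
  kl_single <- kl_set <- ppc <- numeric(3)
  fits_single <- fits_set <- vector("list", 3)
  for (r in seq_len(3)) {
    hold <- holdouts[[r]]
    use <- setdiff(seq_len(n_obs), hold)
    # strategy A: per-observation MAPs, then Gamma MLE
    s_map <- sapply(use, function(i) {
      post <- predict(npe_single, obs[[i]], n_samples = 1000,
                      seed = child_seed(if (is.null(seed)) 0 else seed,
                                        100 + i))
      unname(map_estimate(post)["s_c"])
    })
    fits_single[[r]] <- fit_gamma(s_map)
    kl_single[r] <- kl_gamma(fits_single[[r]], true_dfe)
    # strategy B: joint inference of (alpha, beta, delta_c)
    post_set <- predict(npe_set, obs[use], n_samples = 1000,
                        seed = child_seed(if (is.null(seed)) 0 else seed,
                                          200 + r))
    map_set <- map_estimate(post_set)
    fits_set[[r]] <- gamma_dfe(unname(map_set["alpha"]),
                               unname(map_set["beta"]))
    kl_set[r] <- kl_gamma(fits_set[[r]], true_dfe)
    # out-of-sample PPC for strategy B at the MAP
    rmses <- sapply(hold, function(i) {
      preds <- replicate(n_ppc, {
        s <- pmin(pmax(rgamma(1, shape = fits_set[[r]]$alpha,
                              scale = fits_set[[r]]$beta), 1e-4), 0.4)
        sim <- model$simulate_vec(c(log10(unname(map_set["delta_c"])),
                                    log10(s)))
        sqrt(mean((sim - obs[[i]]$proportion)^2))
      })
      mean(preds)
    })
    ppc[r] <- mean(rmses)
  }
  list(kl_single = kl_single, kl_set = kl_set, ppc_rmse_set = ppc,
       fits_single = fits_single, fits_set = fits_set, s_true = s_true,
       holdouts = holdouts, true_dfe = true_dfe, delta_c = delta_c)
}
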