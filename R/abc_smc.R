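#' Adaptively weighted Euclidean distance
#'
#' Distance between a simulated and an observed summary vector, with each
#' coordinate scaled: `sqrt(sum_t ((sim_t - obs_t) / scale_t)^2)`. During
#' ABC-SMC the scale of coordinate `t` is the root-mean-square deviation of
#' that coordinate across the simulations of the current round, floored at
#' `1e-6` so uninformative (constant) coordinates cannot blow up the
#' distance.
#'
#' @param simulated,observed Numeric vectors on the same grid (or
#'   [trajectory()] objects with matching generations).
#' @param scales Per-coordinate scales; defaults to 1.
#' @return Non-negative scalar distance.
#' @examples
#' adaptive_distance(c(0.3, 0.4), c(0, 0))
#' @export
adaptive_distance <- function(simulated, observed, scales = NULL) {
  if (inherits(simulated, "cnv_trajectory")) {
    if (inherits(observed, "cnv_trajectory") &&
        !isTRUE(all.equal(simulated$generation, observed$generation)))
      stop("trajectories are on different time grids")
    simulated <- simulated$proportion
  }
  if (inherits(observed, "cnv_trajectory")) observed <- observed$proportion
  if (length(simulated) != length(observed))
    stop("summary vectors have different lengths")
  if (is.null(scales)) scales <- rep(1, length(observed))
  scales <- pmax(scales, 1e-6)
  sqrt(sum(((simulated - observed) / scales)^2))
}

# Per-coordinate RMSD scale from a matrix of simulated summaries (rows =
# simulations), floored at 1e-6.
rmsd_scales <- function(sim_matrix) {
  m <- colMeans(sim_matrix)
  pmax(sqrt(colMeans(sweep(sim_matrix, 2, m)^2)), 1e-6)
}

#' Sequential Monte Carlo approximate Bayesian computation
#'
#' Infers `(log10 delta_c, log10 s_c)` (or any box-prior parameter vector)
#' from one observation by ABC-SMC: parameter proposals are drawn from the
#' weighted previous population, perturbed by a component-wise Gaussian
#' kernel (variance twice the weighted empirical variance), simulated, and
#' accepted when their [adaptive_distance()] to the observation falls below
#' the round's threshold. The threshold of each round is the median
#' accepted distance of the previous round; distance scales are re-adapted
#' each round from the previous round's simulations. Inference stops at
#' `epsilon_target` or after `max_rounds` rounds.
#'
#' The per-round population size is adapted to the shape of the current
#' posterior: the next round uses the smallest size (bounded by 100 and
#' `budget / max_rounds`) for which a bootstrap of the current weighted
#' population estimates the posterior mean with coefficient of variation at
#' most 0.05.
#'
#' @param observed A [trajectory()] or numeric summary vector.
#' @param model A [cnv_model()], or a function `f(theta)` returning a
#'   simulated summary vector for a working-space parameter vector.
#' @param prior A [prior_spec()] (or any list with `lower`, `upper`,
#'   `names` in working space).
#' @param budget Total accepted-particle budget (>= 100); the per-round
#'   population is capped at `budget / max_rounds`.
#' @param max_rounds Maximum SMC rounds (default 10).
#' @param epsilon_target Stop once the acceptance threshold reaches this
#'   value (default 0.002).
#' @param n_calibration Prior draws used to calibrate scales and the first
#'   threshold (default 100).
#' @param max_proposal_factor Per-round proposal cap, as a multiple of the
#'   round's population size; exceeding it with zero acceptances signals
#'   failure.
#' @param seed Optional integer seed.
#' @param verbose Print per-round progress.
#'
#' @return A `cnv_posterior` with weighted particles; `diagnostics` holds
#'   the per-round thresholds (`epsilons`), effective sample sizes (`ess`),
#'   population sizes and the total number of simulator calls.
#' @export
abc_smc <- function(observed, model, prior = prior_spec(), budget = 1000,
                    max_rounds = 10, epsilon_target = 0.002,
                    n_calibration = 100, max_proposal_factor = 50,
                    seed = NULL, verbose = FALSE) {
  if (inherits(observed, "cnv_trajectory")) observed <- observed$proportion
  sim_fn <- if (inherits(model, "cnv_model")) model$simulate_vec else model
  if (budget < 100) stop("budget must be at least 100 accepted particles")
  with_seed(seed)
  d <- length(prior$lower)
  widths <- prior$upper - prior$lower
  # degenerate (point) prior: the posterior is that point
  if (all(widths == 0)) {
    return(new_posterior(matrix(prior$lower, 100, d, byrow = TRUE),
                         prior = prior, method = "abc_smc",
                         diagnostics = list(epsilons = numeric(0),
                                            ess = 100, n_sims = 0)))
  }
  pop_cap <- max(100, floor(budget / max_rounds))
  n_sims <- 0

  # calibration: prior draws set the initial scales and threshold
  theta0 <- sample_prior(prior, n_calibration)
  sims0 <- vapply(seq_len(n_calibration),
                  function(i) as.numeric(sim_fn(theta0[i, ])),
                  numeric(length(observed)))
  sims0 <- if (is.matrix(sims0)) t(sims0) else matrix(sims0, ncol = 1)
  n_sims <- n_sims + n_calibration
  scales <- rmsd_scales(sims0)
  d0 <- apply(sims0, 1, adaptive_distance, observed = observed,
              scales = scales)
  eps <- stats::median(d0)
  keep <- d0 <= eps
  particles <- theta0[keep, , drop = FALSE]
  weights <- rep(1 / sum(keep), sum(keep))
  accepted_d <- d0[keep]
  epsilons <- eps
  ess_hist <- 1 / sum(weights^2)
  pop_hist <- sum(keep)
  pop_size <- 100

  for (round in seq_len(max_rounds)) {
    eps <- stats::median(accepted_d)
    if (length(accepted_d) == 0 || !is.finite(eps)) break
    kern_sd <- sqrt(2 * pmax(apply(particles, 2, function(v) {
      m <- weighted.mean(v, weights)
      weighted.mean((v - m)^2, weights)
    }), 1e-12))
    new_particles <- matrix(NA_real_, pop_size, d)
    new_d <- numeric(pop_size)
    sim_store <- vector("list", max_proposal_factor * pop_size)
    n_acc <- 0; n_prop <- 0
    cap <- max_proposal_factor * pop_size
    while (n_acc < pop_size && n_prop < cap) {
      i <- sample.int(nrow(particles), 1, prob = weights)
      cand <- particles[i, ] + rnorm(d, 0, kern_sd)
      if (!all(cand >= prior$lower & cand <= prior$upper)) next
      n_prop <- n_prop + 1
      x <- sim_fn(cand)
      n_sims <- n_sims + 1
      sim_store[[n_prop]] <- x
      dist <- adaptive_distance(x, observed, scales)
      if (dist <= eps) {
        n_acc <- n_acc + 1
        new_particles[n_acc, ] <- cand
        new_d[n_acc] <- dist
      }
    }
    if (n_acc == 0) stop("ABC-SMC failure: no acceptances within the ",
                         "proposal cap in round ", round)
    new_particles <- new_particles[seq_len(n_acc), , drop = FALSE]
    new_d <- new_d[seq_len(n_acc)]
    # importance weights: uniform prior over the box, mixture proposal;
    # computed on the log scale for stability
    log_w <- apply(new_particles, 1, function(th) {
      k <- rep(0, nrow(particles))
      for (j in seq_len(d))
        k <- k + dnorm(th[j], particles[, j], kern_sd[j], log = TRUE)
      m <- max(k)
      -(m + log(sum(weights * exp(k - m))))
    })
    new_w <- exp(log_w - max(log_w))
    new_w <- new_w / sum(new_w)
    particles <- new_particles
    weights <- new_w
    accepted_d <- new_d
    epsilons <- c(epsilons, eps)
    ess_hist <- c(ess_hist, 1 / sum(weights^2))
    pop_hist <- c(pop_hist, n_acc)
    # adapt next-round population size by bootstrap CV of the posterior mean
    scales <- rmsd_scales(do.call(rbind, sim_store[seq_len(n_prop)]))
    pop_size <- adapt_population_size(particles, weights, pop_cap)
    if (verbose)
      message(sprintf("round %d: eps=%.4g acc=%d ess=%.1f next_pop=%d",
                      round, eps, n_acc, tail(ess_hist, 1), pop_size))
    if (eps <= epsilon_target) break
  }
  new_posterior(particles, weights, prior = prior, method = "abc_smc",
                diagnostics = list(epsilons = epsilons, ess = ess_hist,
                                   populations = pop_hist, n_sims = n_sims))
}

# Smallest population size (100..cap) for which bootstrap resamples of the
# weighted population estimate the posterior mean with CV <= 0.05 in every
# dimension. Spread is judged relative to the weighted SD so the criterion
# is scale-free.
adapt_population_size <- function(particles, weights, cap, cv_target = 0.05,
                                  n_boot = 25) {
  sds <- apply(particles, 2, function(v) {
    m <- weighted.mean(v, weights)
    sqrt(max(weighted.mean((v - m)^2, weights), 1e-24))
  })
  for (nn in unique(pmin(c(100, 250, 500, 1000, 2500, 5000, 10000), cap))) {
    cvs <- sapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(particles), nn, replace = TRUE, prob = weights)
      colMeans(particles[idx, , drop = FALSE])
    })
    cv <- apply(rbind(cvs), 1, sd) / sds
    if (all(cv <= cv_target) || nn >= cap) return(as.integer(nn))
  }
  as.integer(cap)
}
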