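#' Generate a training set for neural posterior estimation
#'
#' Draws `n_sims` parameter vectors i.i.d. from the prior and simulates one
#' trajectory per draw with the supplied model. Trajectories are stored
#' raw; per-time-point standardization (mean 0, sd 1 over the training set)
#' is computed and stored when the estimator is fitted.
#'
#' @param prior A [prior_spec()].
#' @param model A [cnv_model()].
#' @param n_sims Number of simulations (the study uses 10,000 or 100,000).
#' @param seed Integer seed; the whole set is reproducible from it.
#' @return An object of class `"cnv_training_set"`: `thetas` (`n_sims x 2`,
#'   log10 scale), `xs` (`n_sims x` time points), `model`, `grid`, `seed`.
#' @export
generate_training_set <- function(prior, model, n_sims, seed = NULL) {
  stopifnot(inherits(model, "cnv_model"), n_sims >= 1)
  with_seed(seed)
  thetas <- sample_prior(prior, n_sims)
  xs <- matrix(0, n_sims, length(model$grid))
  for (i in seq_len(n_sims)) xs[i, ] <- model$simulate_vec(thetas[i, ])
  structure(list(thetas = thetas, xs = xs, prior = prior,
                 model_name = model$model, grid = model$grid,
                 n_sims = n_sims, seed = seed),
            class = "cnv_training_set")
}

#' @export
print.cnv_training_set <- function(x, ...) {
  cat(sprintf("NPE training set: %d simulations (%s model, %d time points)\n",
              x$n_sims, x$model_name, ncol(x$xs)))
  invisible(x)
}

# z-transform between the working space and the unit box used inside the
# density estimator: z = (theta - mid) / halfwidth maps the prior box to
# [-1, 1]^d.
box_transform <- function(prior) {
  mid <- (prior$lower + prior$upper) / 2
  halfwidth <- (prior$upper - prior$lower) / 2
  list(mid = mid, halfwidth = pmax(halfwidth, 1e-12))
}

# Per-time-point standardization. The scale is floored at 1e-3 (roughly the
# resolution of a proportion measurement) so time points that are constant
# in the training set -- e.g. generation 0, always ancestral under the
# Wright-Fisher model -- stay numerically tame when an observation deviates
# there; standardized features are additionally clamped to [-8, 8] so an
# off-manifold observation cannot saturate the network.
standardize_fit <- function(xs) {
  m <- colMeans(xs)
  s <- pmax(apply(xs, 2, sd), 1e-3)
  list(mean = m, sd = s)
}

standardize_apply <- function(xs, std) {
  z <- sweep(sweep(rbind(xs), 2, std$mean), 2, std$sd, "/")
  pmin(pmax(z, -8), 8)
}

#' Fit an amortized neural posterior estimator
#'
#' Trains a conditional density estimator q(theta | x) on the
#' (parameter, simulation) pairs of a training set. Once trained, the
#' estimator evaluates and samples the posterior at any observation of
#' matching dimension without further simulation (amortization).
#'
#' Two estimators are available, both implemented in-package with
#' hand-coded backpropagation:
#' * `"mdn"` (default): a mixture-density network — a dense network whose
#'   output parameterizes a `K`-component diagonal-Gaussian mixture over
#'   the (rescaled) parameters. The classical density estimator for neural
#'   posterior estimation; well suited to the banana-shaped and
#'   prior-truncated posteriors this problem produces.
#' * `"maf"`: an autoregressive conditional-Gaussian estimator
#'   (`q(z1|x) q(z2|z1,x)`, each factor a heteroscedastic Gaussian with
#'   network-predicted mean and scale) — a single-pass affine
#'   autoregressive flow.
#'
#' Training uses minibatch Adam with a held-out validation split and early
#' stopping; a non-finite validation loss aborts with a diagnostic. The
#' mixture is truncated and renormalized on the prior box, so the returned
#' posteriors integrate to 1 over the prior support.
#'
#' @param train A [generate_training_set()] result.
#' @param estimator `"mdn"` or `"maf"`.
#' @param K Mixture components per network (mdn only), default 10.
#' @param hidden Hidden-layer widths of the trunk, default `c(128, 64)`.
#' @param n_ensemble Number of independently initialized networks whose
#'   predictive mixtures are pooled (mdn only, default 1). Pooling widens
#'   the posterior and is offered as a robustness option; the pooled
#'   predictive is still an analytic mixture.
#' @param epochs,batch,lr Maximum epochs (default 400), minibatch size
#'   (128) and Adam learning rate (7e-4).
#' @param val_frac,patience Validation fraction (0.1) and early-stopping
#'   patience in epochs (40).
#' @param seed Integer seed for initialization, data split and batching.
#' @return An object of class `"cnv_npe"`; use [predict.cnv_npe()] to
#'   condition it on an observation.
#' @export
fit_npe <- function(train, estimator = c("mdn", "maf"), K = 10,
                    hidden = c(128, 64), n_ensemble = 1, epochs = 400,
                    batch = 128, lr = 7e-4, val_frac = 0.1, patience = 40,
                    seed = NULL) {
  stopifnot(inherits(train, "cnv_training_set"))
  estimator <- match.arg(estimator)
  std <- standardize_fit(train$xs)
  X <- standardize_apply(train$xs, std)
  bt <- box_transform(train$prior)
  Zt <- sweep(sweep(train$thetas, 2, bt$mid), 2, bt$halfwidth, "/")
  d <- ncol(Zt)
  if (estimator == "mdn") {
    sizes <- c(ncol(X), hidden, mdn_out_dim(K, d))
    acts <- c(rep("tanh", length(hidden)), "linear")
    nets <- lapply(seq_len(n_ensemble), function(e)
      mdn_train(X, Zt, K = K, sizes = sizes, acts = acts,
                epochs = epochs, batch = batch, lr = lr,
                val_frac = val_frac, patience = patience,
                seed = if (is.null(seed)) NULL
                       else child_seed(seed, 7000 + e)))
  } else {
    nets <- vector("list", d)
    for (j in seq_len(d)) {
      Xj <- cbind(X, Zt[, seq_len(j - 1), drop = FALSE])
      sizes <- c(ncol(Xj), hidden, mdn_out_dim(1, 1))
      acts <- c(rep("tanh", length(hidden)), "linear")
      nets[[j]] <- mdn_train(Xj, Zt[, j, drop = FALSE], K = 1,
                             sizes = sizes, acts = acts, epochs = epochs,
                             batch = batch, lr = lr, val_frac = val_frac,
                             patience = patience,
                             seed = if (is.null(seed)) NULL
                                    else child_seed(seed, j))
    }
  }
  structure(list(estimator = estimator, nets = nets, K = K, d = d,
                 std = std, bt = bt, prior = train$prior,
                 model_name = train$model_name, grid = train$grid,
                 n_sims = train$n_sims,
                 val_nll = sapply(nets, `[[`, "val_nll")),
            class = "cnv_npe")
}

#' @export
print.cnv_npe <- function(x, ...) {
  cat(sprintf("Amortized neural posterior estimator (%s)\n", x$estimator))
  cat(sprintf("  trained on %d %s-model simulations; validation NLL %.3f\n",
              x$n_sims, x$model_name, sum(x$val_nll)))
  invisible(x)
}

# Conditional mixture parameters at one standardized observation: Gaussian
# component weights/means/scales plus the pooled weight of the defensive
# uniform component. Ensemble members' predictive mixtures are pooled with
# equal weight (still an analytic mixture).
mdn_condition <- function(npe, x0) {
  pis <- mus <- sigs <- list()
  unif <- 0
  for (e in seq_along(npe$nets)) {
    out <- mlp_forward(npe$nets[[e]]$net, rbind(x0))$out
    p <- mdn_unpack(out, npe$K, npe$d)
    logits <- drop(p$logits)
    w <- exp(logits - max(logits))
    w <- w / sum(w)
    pis[[e]] <- w[seq_len(npe$K)]
    unif <- unif + w[npe$K + 1]
    mus[[e]] <- matrix(p$mu, npe$K, npe$d)
    sigs[[e]] <- matrix(exp(p$logsig), npe$K, npe$d)
  }
  ne <- length(npe$nets)
  list(pi = unlist(pis) / ne, pi_unif = unif / ne,
       mu = do.call(rbind, mus), sig = do.call(rbind, sigs))
}

# Truncated-normal mass of each component over [-1, 1] per dimension.
mdn_box_mass <- function(mu, sig) {
  m <- pnorm((1 - mu) / sig) - pnorm((-1 - mu) / sig)
  apply(pmax(m, 1e-300), 1, prod)
}

#' Evaluate the amortized posterior at an observation
#'
#' Conditions a fitted estimator on one observed trajectory, returning a
#' posterior with an exact (normalized over the prior box) density, an
#' exact sampler, and `n_samples` materialized draws for the particle-based
#' assessment functions. No simulator calls are made.
#'
#' @param object A [fit_npe()] result.
#' @param observed A [trajectory()] on the estimator's grid, or a numeric
#'   vector of matching length.
#' @param n_samples Materialized draws (default 2000).
#' @param seed Optional integer seed for the materialized draws.
#' @param ... Unused.
#' @return A `cnv_posterior`.
#' @export
predict.cnv_npe <- function(object, observed, n_samples = 2000,
                            seed = NULL, ...) {
  if (inherits(observed, "cnv_trajectory")) observed <- observed$proportion
  if (length(observed) != length(object$std$mean))
    stop("observation dimension does not match the training data")
  x0 <- drop(standardize_apply(rbind(observed), object$std))
  bt <- object$bt
  prior <- object$prior
  d <- object$d
  log_jac <- sum(log(bt$halfwidth))
  if (object$estimator == "mdn") {
    cond <- mdn_condition(object, x0)
    mass <- mdn_box_mass(cond$mu, cond$sig)
    # the uniform component has mass 1 on the box by construction
    Znorm <- sum(cond$pi * mass) + cond$pi_unif
    log_density <- function(theta) {
      theta <- rbind(theta)
      z <- sweep(sweep(theta, 2, bt$mid), 2, bt$halfwidth, "/")
      inside <- apply(abs(z) <= 1 + 1e-12, 1, all)
      lp <- rep(-Inf, nrow(z))
      if (any(inside)) {
        zi <- z[inside, , drop = FALSE]
        Kc <- length(cond$pi)
        comp <- matrix(log(cond$pi), nrow(zi), Kc, byrow = TRUE)
        for (k in seq_len(Kc))
          comp[, k] <- comp[, k] +
            rowSums(dnorm(zi, rep(cond$mu[k, ], each = nrow(zi)),
                          rep(cond$sig[k, ], each = nrow(zi)), log = TRUE))
        comp <- cbind(comp, log(cond$pi_unif) + d * log(0.5))
        mx <- apply(comp, 1, max)
        lp[inside] <- mx + log(rowSums(exp(comp - mx))) - log(Znorm) -
          log_jac
      }
      lp
    }
    sampler <- function(n) {
      w <- c(cond$pi * mass, cond$pi_unif) / Znorm
      ks <- sample.int(length(w), n, replace = TRUE, prob = w)
      z <- matrix(runif(n * d, -1, 1), n, d)  # uniform-component draws
      gk <- which(ks <= length(cond$pi))
      for (j in seq_len(d)) {
        mu <- cond$mu[ks[gk], j]; sg <- cond$sig[ks[gk], j]
        lo <- pnorm((-1 - mu) / sg); hi <- pnorm((1 - mu) / sg)
        z[gk, j] <- mu + sg * qnorm(lo + runif(length(gk)) * (hi - lo))
      }
      z <- pmin(pmax(z, -1), 1)
      th <- sweep(sweep(z, 2, bt$halfwidth, "*"), 2, bt$mid, "+")
      colnames(th) <- prior$names
      th
    }
  } else {
    # per-dimension conditional: a Gaussian plus the defensive uniform
    cond_par <- function(j, zprev) {
      inp <- cbind(matrix(x0, nrow(zprev), length(x0), byrow = TRUE),
                   zprev)
      out <- mlp_forward(object$nets[[j]]$net, inp)$out
      lg <- out[, 1:2, drop = FALSE]
      w <- exp(lg - apply(lg, 1, max))
      w <- w / rowSums(w)
      list(w_g = w[, 1], w_u = w[, 2], mu = out[, 3],
           sig = exp(pmin(pmax(out[, 4], -6), 2.5)))
    }
    log_density <- function(theta) {
      theta <- rbind(theta)
      z <- sweep(sweep(theta, 2, bt$mid), 2, bt$halfwidth, "/")
      inside <- apply(abs(z) <= 1 + 1e-12, 1, all)
      lp <- rep(-Inf, nrow(z))
      if (any(inside)) {
        zi <- z[inside, , drop = FALSE]
        tot <- rep(-log_jac, nrow(zi))
        for (j in seq_len(d)) {
          cp <- cond_par(j, zi[, seq_len(j - 1), drop = FALSE])
          m <- pmax(pnorm((1 - cp$mu) / cp$sig) -
                      pnorm((-1 - cp$mu) / cp$sig), 1e-300)
          dens <- (cp$w_g * dnorm(zi[, j], cp$mu, cp$sig) + cp$w_u * 0.5) /
            (cp$w_g * m + cp$w_u)
          tot <- tot + log(dens)
        }
        lp[inside] <- tot
      }
      lp
    }
    sampler <- function(n) {
      z <- matrix(0, n, d)
      for (j in seq_len(d)) {
        cp <- cond_par(j, z[, seq_len(j - 1), drop = FALSE])
        m <- pmax(pnorm((1 - cp$mu) / cp$sig) -
                    pnorm((-1 - cp$mu) / cp$sig), 1e-300)
        p_g <- cp$w_g * m / (cp$w_g * m + cp$w_u)
        use_g <- runif(n) < p_g
        lo <- pnorm((-1 - cp$mu) / cp$sig)
        hi <- pnorm((1 - cp$mu) / cp$sig)
        zg <- cp$mu + cp$sig * qnorm(lo + runif(n) * (hi - lo))
        z[, j] <- ifelse(use_g, zg, runif(n, -1, 1))
      }
      z <- pmin(pmax(z, -1), 1)
      th <- sweep(sweep(z, 2, bt$halfwidth, "*"), 2, bt$mid, "+")
      colnames(th) <- prior$names
      th
    }
  }
  with_seed(seed)
  samples <- sampler(n_samples)
  new_posterior(samples, log_density = log_density, sampler = sampler,
                prior = prior, method = paste0("npe_", object$estimator),
                diagnostics = list(val_nll = object$val_nll,
                                   n_train = object$n_sims))
}
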