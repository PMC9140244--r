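#' Prior for hierarchical (observation-set) inference
#'
#' Joint prior over the Gamma DFE shape `alpha` (uniform on 0.5-15), scale
#' `beta` (log-uniform on 1e-3 to 0.8) and the focal formation rate
#' `delta_c` (log-uniform on 1e-12 to 1e-3). The working space is
#' `(alpha, log10 beta, log10 delta_c)`.
#'
#' @return A prior object as used by the inference engines.
#' @export
hier_prior <- function() {
  structure(list(lower = c(0.5, -3, -12),
                 upper = c(15, log10(0.8), -3),
                 names = c("alpha", "log10_beta", "log10_delta_c")),
            class = "prior_spec")
}

#' Training set for observation-set inference
#'
#' Each training example pairs a draw of `(alpha, log10 beta,
#' log10 delta_c)` with a set of `n_obs` trajectories simulated under the
#' Wright-Fisher model, each with its own selection coefficient drawn from
#' `Gamma(alpha, beta)` (draws outside the single-observation prior support
#' for `s_c` are clipped to it). The trajectories of a set are
#' concatenated into one feature vector.
#'
#' @param model A [cnv_model()] (the study uses the Wright-Fisher model).
#' @param n_sims Number of parameter draws (sets).
#' @param n_obs Trajectories per set (default 8, the number of experiments
#'   used for direct DFE inference after holding 3 of 11 out).
#' @param prior A [hier_prior()].
#' @param s_bounds Natural-scale clipping bounds for drawn selection
#'   coefficients (default the single-observation prior `c(1e-4, 0.4)`).
#' @param seed Integer seed.
#' @return A `"cnv_training_set"` whose `xs` rows are concatenated sets.
#' @export
generate_set_training_set <- function(model, n_sims, n_obs = 8,
                                      prior = hier_prior(),
                                      s_bounds = c(1e-4, 0.4),
                                      seed = NULL) {
  stopifnot(inherits(model, "cnv_model"), n_sims >= 1)
  with_seed(seed)
  thetas <- sample_prior(prior, n_sims)
  p <- length(model$grid)
  xs <- matrix(0, n_sims, n_obs * p)
  for (i in seq_len(n_sims)) {
    alpha <- thetas[i, 1]
    beta <- 10^thetas[i, 2]
    l10d <- thetas[i, 3]
    s <- pmin(pmax(rgamma(n_obs, shape = alpha, scale = beta),
                   s_bounds[1]), s_bounds[2])
    for (j in seq_len(n_obs))
      xs[i, (j - 1) * p + seq_len(p)] <-
        model$simulate_vec(c(l10d, log10(s[j])))
  }
  structure(list(thetas = thetas, xs = xs, prior = prior,
                 model_name = model$model, grid = model$grid,
                 n_obs = n_obs, n_sims = n_sims, seed = seed),
            class = "cnv_training_set")
}

#' Fit an amortized estimator for observation sets
#'
#' Like [fit_npe()], but the condition is a set of trajectories reduced to
#' a 5-feature summary by an embedding network trained jointly with the
#' density estimator: three dense layers (rectified-linear activations
#' between them) map the concatenated set to 5 features, which feed the
#' mixture-density head through one further hidden layer. The posterior is
#' over `(alpha, log10 beta, log10 delta_c)`.
#'
#' @param train A [generate_set_training_set()] result.
#' @param K Mixture components (default 8).
#' @param embed_hidden Widths of the two hidden embedding layers
#'   (default `c(64, 64)`).
#' @param embed_dim Summary width (default 5).
#' @param head_hidden Hidden width between summary and mixture head
#'   (default 64).
#' @inheritParams fit_npe
#' @return An object of class `c("cnv_npe_set", "cnv_npe")`.
#' @export
fit_npe_set <- function(train, K = 8, embed_hidden = c(64, 64),
                        embed_dim = 5, head_hidden = 64, epochs = 400,
                        batch = 128, lr = 7e-4, val_frac = 0.1,
                        patience = 40, seed = NULL) {
  stopifnot(inherits(train, "cnv_training_set"), !is.null(train$n_obs))
  std <- standardize_fit(train$xs)
  X <- standardize_apply(train$xs, std)
  bt <- box_transform(train$prior)
  Zt <- sweep(sweep(train$thetas, 2, bt$mid), 2, bt$halfwidth, "/")
  d <- ncol(Zt)
  sizes <- c(ncol(X), embed_hidden, embed_dim, head_hidden,
             mdn_out_dim(K, d))
  acts <- c(rep("relu", length(embed_hidden)), "linear", "tanh", "linear")
  fit <- mdn_train(X, Zt, K = K, sizes = sizes, acts = acts,
                   epochs = epochs, batch = batch, lr = lr,
                   val_frac = val_frac, patience = patience, seed = seed)
  structure(list(estimator = "mdn", nets = list(fit), K = K, d = d,
                 std = std, bt = bt, prior = train$prior,
                 model_name = train$model_name, grid = train$grid,
                 n_obs = train$n_obs, n_sims = train$n_sims,
                 summary_layer = length(embed_hidden) + 1,
                 val_nll = fit$val_nll),
            class = c("cnv_npe_set", "cnv_npe"))
}

# Flatten a list of trajectories (or a matrix with one row per trajectory)
# into the concatenated feature vector the set estimator expects.
flatten_obs_set <- function(object, obs_set) {
  p <- length(object$grid)
  if (is.list(obs_set)) {
    if (length(obs_set) != object$n_obs)
      stop("observation set must contain exactly ", object$n_obs,
           " trajectories")
    vecs <- lapply(obs_set, function(tr) {
      if (inherits(tr, "cnv_trajectory")) tr$proportion else as.numeric(tr)
    })
    if (any(lengths(vecs) != p)) stop("trajectories are not on the common grid")
    unlist(vecs)
  } else {
    as.numeric(t(rbind(obs_set)))
  }
}

#' @rdname fit_npe_set
#' @param object A fitted `cnv_npe_set`.
#' @param observed A list of `n_obs` trajectories on the common grid.
#' @param n_samples,... Passed to the single-observation method.
#' @param seed Optional integer seed.
#' @export
predict.cnv_npe_set <- function(object, observed, n_samples = 2000,
                                seed = NULL, ...) {
  x <- flatten_obs_set(object, observed)
  predict.cnv_npe(object, x, n_samples = n_samples, seed = seed, ...)
}

#' Summary features of an observation set
#'
#' Applies the trained embedding network of a set estimator to one
#' observation set, returning its learned 5-feature summary (the input the
#' density estimator actually conditions on). Deterministic given the
#' fitted estimator; the reduction is not symmetric in the set order (the
#' embedding is a plain dense network over the concatenated set).
#'
#' @param object A fitted [fit_npe_set()] estimator.
#' @param obs_set A list of `n_obs` trajectories on the common grid.
#' @return Numeric vector of length `embed_dim` (default 5).
#' @export
summarize_observation_set <- function(object, obs_set) {
  stopifnot(inherits(object, "cnv_npe_set"))
  x <- flatten_obs_set(object, obs_set)
  x0 <- standardize_apply(rbind(x), object$std)
  cache <- mlp_forward(object$nets[[1]]$net, x0)
  drop(cache$A[[object$summary_layer]])
}
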