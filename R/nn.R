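# Minimal dense-network machinery used by the neural posterior estimator:
# a fully connected network with per-layer activations, hand-coded
# backpropagation, Adam updates and early stopping. Everything is plain
# matrix algebra on the R side; no external dependencies.

# sizes: c(in, h1, ..., out); acts: activation per layer (length = #layers),
# one of "tanh", "relu", "linear".
mlp_init <- function(sizes, acts, seed = NULL) {
  with_seed(seed)
  n_layers <- length(sizes) - 1
  stopifnot(length(acts) == n_layers)
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fan_in <- sizes[l]
    sc <- if (acts[l] == "relu") sqrt(2 / fan_in) else sqrt(1 / fan_in)
    if (l == n_layers) sc <- 0.01  # small head init; biases set by caller
    W[[l]] <- matrix(rnorm(fan_in * sizes[l + 1], 0, sc), fan_in,
                     sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b, acts = acts, sizes = sizes)
}

act_fun <- function(z, act) {
  switch(act, tanh = tanh(z), relu = pmax(z, 0), linear = z,
         stop("unknown activation"))
}

# X: n x in. Returns activations A[[l]] (post-activation) for each layer,
# with A[[0]] = X kept separately in the cache.
mlp_forward <- function(net, X) {
  L <- length(net$W)
  A <- vector("list", L)
  Zs <- vector("list", L)
  cur <- X
  for (l in seq_len(L)) {
    Z <- cur %*% net$W[[l]]
    Z <- sweep(Z, 2, net$b[[l]], "+")
    Zs[[l]] <- Z
    cur <- act_fun(Z, net$acts[l])
    A[[l]] <- cur
  }
  list(out = cur, A = A, Z = Zs, X = X)
}

# dOut: gradient of the loss wrt the network output (n x out).
# Returns per-parameter gradients and the gradient wrt the input.
mlp_backward <- function(net, cache, dOut) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    delta <- switch(net$acts[l],
                    tanh = delta * (1 - cache$A[[l]]^2),
                    relu = delta * (cache$Z[[l]] > 0),
                    linear = delta)
    inp <- if (l == 1) cache$X else cache$A[[l - 1]]
    gW[[l]] <- crossprod(inp, delta)
    gb[[l]] <- colSums(delta)
    delta <- delta %*% t(net$W[[l]])
  }
  list(gW = gW, gb = gb, dX = delta)
}

adam_init <- function(net) {
  zero <- function(p) lapply(p, function(m) m * 0)
  list(mW = zero(net$W), vW = zero(net$W), mb = zero(net$b),
       vb = zero(net$b), t = 0)
}

adam_step <- function(net, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$gW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$gW[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (state$mW[[l]] / bc1) /
      (sqrt(state$vW[[l]] / bc2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$gb[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$gb[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (state$mb[[l]] / bc1) /
      (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(net = net, state = state)
}

# ---- mixture-density head ---------------------------------------------------

# The network output parameterizes a mixture over a d-dimensional target
# living in the box [-1, 1]^d: K diagonal-Gaussian components plus one
# "defensive" uniform component over the box (which captures the flat,
# prior-dominated posteriors that arise when an observation carries little
# information). Columns 1..K+1 are component logits (K+1 is the uniform
# component), then K*d means, then K*d log-sds (component-major within
# each block).
mdn_unpack <- function(out, K, d) {
  n <- nrow(out)
  logits <- out[, 1:(K + 1), drop = FALSE]
  off <- K + 1
  mu <- array(out[, off + 1:(K * d)], dim = c(n, K, d))
  logsig <- array(out[, off + K * d + 1:(K * d)], dim = c(n, K, d))
  logsig <- pmin(pmax(logsig, -6), 2.5)
  list(logits = logits, mu = mu, logsig = logsig)
}

mdn_out_dim <- function(K, d) (K + 1) + 2 * K * d

# n x d slice for component k (robust to n = 1).
mdn_slice <- function(arr, k, n, d) {
  m <- arr[, k, , drop = FALSE]
  dim(m) <- c(n, d)
  m
}

# Per-sample mixture log-density of targets Z (n x d) and, optionally, the
# gradient of the mean NLL wrt the raw network output.
mdn_logdens <- function(out, Z, K, d, grad = FALSE) {
  out <- rbind(out); Z <- rbind(Z)
  n <- nrow(out)
  p <- mdn_unpack(out, K, d)
  lse <- function(m) {
    mx <- apply(m, 1, max)
    mx + log(rowSums(exp(m - mx)))
  }
  logpi <- p$logits - lse(p$logits)
  comp <- logpi
  for (k in seq_len(K)) {
    mu_k <- mdn_slice(p$mu, k, n, d)
    ls_k <- mdn_slice(p$logsig, k, n, d)
    comp[, k] <- comp[, k] +
      rowSums(-0.918938533204673 - ls_k -
                0.5 * ((Z - mu_k) / exp(ls_k))^2)
  }
  comp[, K + 1] <- comp[, K + 1] + d * log(0.5)  # uniform on [-1, 1]^d
  logp <- lse(comp)
  if (!grad) return(list(logp = logp))
  r <- exp(comp - logp)  # responsibilities, n x (K + 1)
  dOut <- matrix(0, n, ncol(out))
  dOut[, 1:(K + 1)] <- r - exp(logpi)
  off <- K + 1
  for (k in seq_len(K)) {
    mu_k <- mdn_slice(p$mu, k, n, d)
    s_k <- exp(mdn_slice(p$logsig, k, n, d))
    zc <- (Z - mu_k) / s_k
    for (j in seq_len(d)) {
      dOut[, off + (j - 1) * K + k] <- r[, k] * zc[, j] / s_k[, j]
      dOut[, off + K * d + (j - 1) * K + k] <- r[, k] * (zc[, j]^2 - 1)
    }
  }
  # gradient of mean NLL = -(1/n) * d logp
  list(logp = logp, dOut = -dOut / n)
}

# Train a dense network with a mixture-density head by minibatch Adam with
# a validation split and early stopping; returns the best-validation net.
# hidden: trunk widths; bottleneck: optional c(position_width) embedding
# handled by the caller through `sizes`/`acts` directly.
mdn_train <- function(X, Z, K = 8, sizes, acts, epochs = 300, batch = 256,
                      lr = 1e-3, val_frac = 0.1, patience = 20,
                      seed = NULL, verbose = FALSE) {
  with_seed(seed)
  n <- nrow(X); d <- ncol(Z)
  net <- mlp_init(sizes, acts)
  # spread component means over the target range at init
  L <- length(net$W)
  head_b <- net$b[[L]]
  head_b[1:(K + 1)] <- 0
  head_b[K + 1 + 1:(K * d)] <- runif(K * d, -0.8, 0.8)
  head_b[K + 1 + K * d + 1:(K * d)] <- log(0.5)
  net$b[[L]] <- head_b
  idx <- sample.int(n)
  n_val <- max(1, floor(val_frac * n))
  val_i <- idx[seq_len(n_val)]
  tr_i <- idx[-seq_len(n_val)]
  Xtr <- X[tr_i, , drop = FALSE]; Ztr <- Z[tr_i, , drop = FALSE]
  Xva <- X[val_i, , drop = FALSE]; Zva <- Z[val_i, , drop = FALSE]
  st <- adam_init(net)
  best <- net; best_val <- Inf; wait <- 0
  hist <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(nrow(Xtr))
    for (start in seq(1, nrow(Xtr), by = batch)) {
      bi <- ord[start:min(start + batch - 1, nrow(Xtr))]
      cache <- mlp_forward(net, Xtr[bi, , drop = FALSE])
      md <- mdn_logdens(cache$out, Ztr[bi, , drop = FALSE], K, d,
                        grad = TRUE)
      if (any(!is.finite(md$dOut))) next
      g <- mlp_backward(net, cache, md$dOut)
      up <- adam_step(net, g, st, lr = lr)
      net <- up$net; st <- up$state
    }
    val <- -mean(mdn_logdens(mlp_forward(net, Xva)$out, Zva, K, d)$logp)
    hist <- c(hist, val)
    if (!is.finite(val))
      stop("training divergence: validation loss is not finite at epoch ",
           ep)
    if (val < best_val - 1e-4) {
      best_val <- val; best <- net; wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) break
    }
    if (verbose && ep %% 10 == 0)
      message(sprintf("epoch %d: val NLL %.4f", ep, val))
  }
  list(net = best, val_nll = best_val, history = hist, K = K, d = d)
}
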