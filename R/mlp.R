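# Minimal feed-forward network engine used for the base models and the
# MLP meta-learner. Written in plain R matrix algebra: the stacking method
# needs direct access to penultimate-layer activations and output-layer
# weights, and the problem sizes involved (<= a few hundred samples,
# layers of width <= 128) make vectorised R entirely adequate.
#
# Conventions: X is n x d; each dense layer holds W (d_in x d_out) and b
# (length d_out); optional batch normalization sits between the linear map
# and the activation; inverted dropout follows the activation during
# training. Final layer is sigmoid per head with binary cross-entropy.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

nn_new <- function(input_dim, layer_sizes, activations,
                   batchnorm = rep(FALSE, length(layer_sizes)),
                   dropout = rep(0, length(layer_sizes))) {
  stopifnot(length(layer_sizes) == length(activations),
            length(batchnorm) == length(layer_sizes),
            length(dropout) == length(layer_sizes))
  dims <- c(input_dim, layer_sizes)
  layers <- vector("list", length(layer_sizes))
  for (l in seq_along(layer_sizes)) {
    fan_in <- dims[l]; fan_out <- dims[l + 1]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * fan_out, 0, sqrt(2 / (fan_in + fan_out))),
                 fan_in, fan_out),
      b = rep(0, fan_out),
      activation = activations[[l]],
      batchnorm = isTRUE(batchnorm[[l]]),
      dropout = dropout[[l]]
    )
    if (layers[[l]]$batchnorm) {
      layers[[l]]$gamma <- rep(1, fan_out)
      layers[[l]]$beta <- rep(0, fan_out)
      layers[[l]]$run_mean <- rep(0, fan_out)
      layers[[l]]$run_var <- rep(1, fan_out)
    }
  }
  structure(list(layers = layers, input_dim = input_dim), class = "vf_nn")
}

nn_activate <- function(Z, act) {
  switch(act,
         sigmoid = 1 / (1 + exp(-Z)),
         relu = pmax(Z, 0),
         softmax = {
           E <- exp(Z - apply(Z, 1, max))
           E / rowSums(E)
         },
         linear = Z,
         stop_vf("unknown activation '%s'", act))
}

# Forward pass. training = TRUE uses batch statistics and samples dropout
# masks (caller must manage the RNG stream); otherwise running statistics
# and no dropout. Returns activations and caches for backprop.
nn_forward <- function(net, X, training = FALSE) {
  caches <- vector("list", length(net$layers))
  A <- X
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    Z <- A %*% ly$W
    Z <- sweep(Z, 2, ly$b, "+")
    cache <- list(A_prev = A)
    if (ly$batchnorm) {
      if (training) {
        mu <- colMeans(Z)
        v <- colMeans(sweep(Z, 2, mu)^2)
        cache$mu <- mu; cache$v <- v
      } else {
        mu <- ly$run_mean; v <- ly$run_var
      }
      xhat <- sweep(sweep(Z, 2, mu), 2, sqrt(v + BN_EPS), "/")
      cache$xhat <- xhat
      Z <- sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
    }
    cache$Z <- Z
    A <- nn_activate(Z, ly$activation)
    cache$A <- A
    if (training && ly$dropout > 0) {
      mask <- matrix(stats::rbinom(length(A), 1, 1 - ly$dropout),
                     nrow(A), ncol(A)) / (1 - ly$dropout)
      A <- A * mask
      cache$mask <- mask
    }
    caches[[l]] <- cache
  }
  list(output = A, caches = caches)
}

nn_bce <- function(P, Y) {
  P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  -mean(Y * log(P) + (1 - Y) * log(1 - P))
}

# Backward pass for sigmoid-output + BCE. Returns per-layer gradients and
# batch-norm running-stat updates.
nn_backward <- function(net, fw, Y) {
  L <- length(net$layers)
  n <- nrow(Y)
  grads <- vector("list", L)
  # combined sigmoid+BCE gradient at the final pre-activation
  P <- fw$caches[[L]]$A
  dZ <- (P - Y) / (n * ncol(Y))
  for (l in L:1) {
    ly <- net$layers[[l]]
    cache <- fw$caches[[l]]
    if (l < L) {
      dA <- dZ   # dZ here is gradient wrt this layer's (dropped-out) output
      if (!is.null(cache$mask)) dA <- dA * cache$mask
      A <- cache$A
      dZ <- switch(ly$activation,
                   sigmoid = dA * A * (1 - A),
                   relu = dA * (cache$Z > 0),
                   softmax = {
                     s <- rowSums(dA * A)
                     A * (dA - s)
                   },
                   linear = dA)
    }
    g <- list()
    if (ly$batchnorm) {
      xhat <- cache$xhat
      g$gamma <- colSums(dZ * xhat)
      g$beta <- colSums(dZ)
      dxhat <- sweep(dZ, 2, ly$gamma, "*")
      inv_sd <- 1 / sqrt(cache$v + BN_EPS)
      m <- nrow(dZ)
      dZ <- sweep(
        m * dxhat - matrix(colSums(dxhat), m, ncol(dZ), byrow = TRUE) -
          xhat * matrix(colSums(dxhat * xhat), m, ncol(dZ), byrow = TRUE),
        2, inv_sd / m, "*")
      g$run_mean <- cache$mu
      g$run_var <- cache$v
    }
    g$W <- crossprod(cache$A_prev, dZ)
    g$b <- colSums(dZ)
    grads[[l]] <- g
    if (l > 1) dZ <- dZ %*% t(ly$W)   # gradient wrt previous layer output
  }
  grads
}

opt_new <- function(kind = c("adam", "sgd", "rmsprop"), lr,
                    weight_decay = 0) {
  kind <- match.arg(kind)
  list(kind = kind, lr = lr, weight_decay = weight_decay, t = 0,
       state = list())
}

opt_step <- function(opt, net, grads) {
  opt$t <- opt$t + 1
  for (l in seq_along(net$layers)) {
    for (p in c("W", "b", "gamma", "beta")) {
      if (is.null(grads[[l]][[p]])) next
      g <- grads[[l]][[p]]
      if (p == "W" && opt$weight_decay > 0) {
        g <- g + opt$weight_decay * net$layers[[l]][[p]]
      }
      key <- paste(l, p)
      s <- opt$state[[key]] %||% list(m = g * 0, v = g * 0)
      if (opt$kind == "sgd") {
        upd <- opt$lr * g
      } else if (opt$kind == "rmsprop") {
        s$v <- 0.9 * s$v + 0.1 * g^2
        upd <- opt$lr * g / (sqrt(s$v) + 1e-8)
      } else {
        s$m <- 0.9 * s$m + 0.1 * g
        s$v <- 0.999 * s$v + 0.001 * g^2
        mhat <- s$m / (1 - 0.9^opt$t)
        vhat <- s$v / (1 - 0.999^opt$t)
        upd <- opt$lr * mhat / (sqrt(vhat) + 1e-8)
      }
      opt$state[[key]] <- s
      net$layers[[l]][[p]] <- net$layers[[l]][[p]] - upd
    }
    if (net$layers[[l]]$batchnorm && !is.null(grads[[l]]$run_mean)) {
      net$layers[[l]]$run_mean <- BN_MOMENTUM * net$layers[[l]]$run_mean +
        (1 - BN_MOMENTUM) * grads[[l]]$run_mean
      net$layers[[l]]$run_var <- BN_MOMENTUM * net$layers[[l]]$run_var +
        (1 - BN_MOMENTUM) * grads[[l]]$run_var
    }
  }
  list(opt = opt, net = net)
}

# Train a network with mini-batch gradient descent, optional validation
# split and early stopping on validation loss. Deterministic given seed.
# Returns net + training log.
nn_fit <- function(input_dim, layer_sizes, activations, X, Y,
                   batchnorm = rep(FALSE, length(layer_sizes)),
                   dropout = rep(0, length(layer_sizes)),
                   epochs = 25, batch_size = 32, lr = 1e-3,
                   optimizer = "adam", weight_decay = 0,
                   patience = Inf, val_fraction = 0.15, seed = 1) {
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), ncol(X) == input_dim)
  with_local_seed(seed, {
    net <- nn_new(input_dim, layer_sizes, activations, batchnorm, dropout)
    n <- nrow(X)
    use_val <- is.finite(patience) && val_fraction > 0 && n >= 10
    if (use_val) {
      n_val <- max(2L, floor(n * val_fraction))
      val_idx <- sample(n, n_val)
      Xv <- X[val_idx, , drop = FALSE]; Yv <- Y[val_idx, , drop = FALSE]
      Xt <- X[-val_idx, , drop = FALSE]; Yt <- Y[-val_idx, , drop = FALSE]
    } else {
      Xt <- X; Yt <- Y; Xv <- NULL
    }
    opt <- opt_new(optimizer, lr, weight_decay)
    log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0))
    best <- list(loss = Inf, net = net, epoch = 0)
    stale <- 0
    for (ep in seq_len(epochs)) {
      ord <- sample(nrow(Xt))
      for (start in seq(1, nrow(Xt), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, nrow(Xt))]
        fw <- nn_forward(net, Xt[idx, , drop = FALSE], training = TRUE)
        grads <- nn_backward(net, fw, Yt[idx, , drop = FALSE])
        st <- opt_step(opt, net, grads)
        opt <- st$opt; net <- st$net
      }
      tr_loss <- nn_bce(nn_forward(net, Xt)$output, Yt)
      va_loss <- if (use_val) nn_bce(nn_forward(net, Xv)$output, Yv) else NA
      log <- rbind(log, data.frame(epoch = ep, train_loss = tr_loss,
                                   val_loss = va_loss))
      if (use_val) {
        if (va_loss < best$loss - 1e-9) {
          best <- list(loss = va_loss, net = net, epoch = ep)
          stale <- 0
        } else {
          stale <- stale + 1
          if (stale >= patience) break
        }
      }
    }
    if (use_val && is.finite(best$loss)) net <- best$net
    list(net = net, log = log,
         stopped_epoch = if (use_val) best$epoch else epochs)
  })
}

nn_predict <- function(net, X) {
  nn_forward(net, X, training = FALSE)$output
}

# Activations of the penultimate layer (input to the output layer),
# computed in inference mode.
nn_penultimate <- function(net, X) {
  L <- length(net$layers)
  fw <- nn_forward(net, X, training = FALSE)
  if (L == 1) return(X)
  fw$caches[[L - 1]]$A
}
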