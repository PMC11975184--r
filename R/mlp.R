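# Multi-output feedforward network: ReLU hidden layers, linear output,
# full-batch Adam on the L2-regularized half-MSE loss (see loss_mse_l2).
# Written in plain matrix algebra; the problem sizes here (hundreds of
# samples, tens of thousands of weights) need nothing more.

mlp_init <- function(n_in, hidden, n_out, seed) {
  sizes <- c(n_in, hidden, n_out)
  with_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1L)) {
      limit <- sqrt(6 / (sizes[l] + sizes[l + 1L]))  # Glorot uniform
      W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -limit, limit),
                       nrow = sizes[l])
      b[[l]] <- rep(0, sizes[l + 1L])
    }
    list(W = W, b = b)
  })
}

mlp_forward <- function(net, X) {
  L <- length(net$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- acts[[l]] %*% net$W[[l]]
    Z <- sweep(Z, 2, net$b[[l]], "+")
    acts[[l + 1L]] <- if (l < L) pmax(Z, 0) else Z
  }
  acts
}

mlp_weight_norm_sq <- function(net) sum(vapply(net$W, function(w) sum(w^2), numeric(1)))

# X, Y: scaled matrices. Returns the fitted net with training trace.
mlp_fit <- function(X, Y, hidden = c(100, 50, 25, 50, 100), alpha = 0.1,
                    learning_rate = 0.01, max_epochs = 2000L, tol = 1e-6,
                    n_iter_no_change = 250L, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  net <- mlp_init(ncol(X), hidden, ncol(Y), seed)
  L <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best <- Inf; stall <- 0L; t <- 0L
  loss_trace <- numeric(0)

  for (epoch in seq_len(max_epochs)) {
    acts <- mlp_forward(net, X)
    resid <- acts[[L + 1L]] - Y
    loss <- sum(resid^2) / (2 * n) + alpha * mlp_weight_norm_sq(net) / (2 * n)
    loss_trace[epoch] <- loss

    # backprop
    delta <- resid / n
    gW <- vector("list", L); gb <- vector("list", L)
    for (l in L:1) {
      gW[[l]] <- crossprod(acts[[l]], delta) + (alpha / n) * net$W[[l]]
      gb[[l]] <- colSums(delta)
      if (l > 1L) {
        delta <- (delta %*% t(net$W[[l]])) * (acts[[l]] > 0)
      }
    }
    # Adam update
    t <- t + 1L
    c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
    for (l in seq_len(L)) {
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
      net$W[[l]] <- net$W[[l]] - learning_rate * (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + eps)
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
      net$b[[l]] <- net$b[[l]] - learning_rate * (mb[[l]] / c1) / (sqrt(vb[[l]] / c2) + eps)
    }

    if (loss > best - tol) stall <- stall + 1L else stall <- 0L
    if (loss < best) best <- loss
    if (stall >= n_iter_no_change) break
  }
  net$hidden <- hidden; net$alpha <- alpha
  net$n_epochs <- length(loss_trace)
  net$final_loss <- loss_trace[length(loss_trace)]
  net
}

mlp_predict <- function(net, X) {
  acts <- mlp_forward(net, as.matrix(X))
  acts[[length(acts)]]
}
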