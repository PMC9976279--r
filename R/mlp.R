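# A small feed-forward regressor: three densely connected hidden layers of
# strictly decreasing width, ReLU activations, Adam optimizer, mean-squared
# error loss, with best-validation-epoch checkpointing. Written in plain R
# matrix operations; the data sizes in this package (hundreds to a few
# thousand molecules, tens of descriptors) do not need a GPU framework.

.relu <- function(x) pmax(x, 0)

.mlp_init <- function(d_in, widths) {
  sizes <- c(d_in, widths, 1L)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    # He-normal initialization, suited to ReLU layers
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b)
}

.mlp_forward <- function(par, X) {
  a <- X
  L <- length(par$W)
  acts <- vector("list", L + 1L)
  acts[[1]] <- a
  for (l in seq_len(L)) {
    z <- sweep(a %*% par$W[[l]], 2, par$b[[l]], `+`)
    a <- if (l < L) .relu(z) else z
    acts[[l + 1]] <- a
  }
  list(yhat = as.numeric(a), acts = acts)
}

.mlp_grad <- function(par, acts, err) {
  # err = dLoss/dyhat for MSE: 2 * (yhat - y) / n
  L <- length(par$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- matrix(err, ncol = 1)
  for (l in rev(seq_len(L))) {
    a_prev <- acts[[l]]
    gW[[l]] <- crossprod(a_prev, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(par$W[[l]])) * (acts[[l]] > 0)
    }
  }
  list(W = gW, b = gb)
}

#' Fit the feed-forward network
#'
#' @param X numeric feature matrix (pre-scaled by the caller).
#' @param y numeric response.
#' @param widths three strictly decreasing hidden-layer widths.
#' @param lr Adam learning rate.
#' @param epochs training epochs; the weights from the epoch with the best
#'   validation MSE are kept.
#' @param batch_size minibatch size.
#' @param val_frac fraction of rows held out for epoch checkpointing.
#' @param seed integer seed (initialization, shuffling, validation split).
#' @return internal fit object used by [fit_model()].
#' @keywords internal
mlp_fit <- function(X, y, widths = c(128L, 64L, 32L), lr = 1e-3,
                    epochs = 200L, batch_size = 32L, val_frac = 0.15,
                    seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y), length(widths) == 3,
            all(diff(widths) < 0), all(widths > 0), lr > 0, epochs >= 1)
  n <- nrow(X)
  with_local_seed(seed, {
    n_val <- max(1L, floor(n * val_frac))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (length(tr_idx) < 2L) { tr_idx <- seq_len(n); val_idx <- seq_len(n) }
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    Xva <- X[val_idx, , drop = FALSE]; yva <- y[val_idx]

    par <- .mlp_init(ncol(X), as.integer(widths))
    mW <- lapply(par$W, function(w) w * 0); vW <- mW
    mb <- lapply(par$b, function(b) b * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_step <- 0
    best <- list(par = par, val = Inf)

    for (epoch in seq_len(epochs)) {
      ord <- sample(length(ytr))
      for (start in seq(1, length(ytr), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, length(ytr))]
        fw <- .mlp_forward(par, Xtr[idx, , drop = FALSE])
        err <- 2 * (fw$yhat - ytr[idx]) / length(idx)
        g <- .mlp_grad(par, fw$acts, err)
        t_step <- t_step + 1
        corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
        for (l in seq_along(par$W)) {
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * g$W[[l]]
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * g$W[[l]]^2
          par$W[[l]] <- par$W[[l]] -
            lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * g$b[[l]]
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * g$b[[l]]^2
          par$b[[l]] <- par$b[[l]] -
            lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
        }
      }
      val_mse <- mean((.mlp_forward(par, Xva)$yhat - yva)^2)
      if (val_mse < best$val) best <- list(par = par, val = val_mse)
    }
    list(par = best$par, val_mse = best$val, widths = as.integer(widths))
  })
}

mlp_predict <- function(fit, X) {
  .mlp_forward(fit$par, X)$yhat
}
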