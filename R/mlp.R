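# Feed-forward neural networks for binary classification, written directly
# on base-R matrix algebra: ReLU hidden layers, sigmoid output trained with
# binary cross-entropy and Adam. Supports inverted dropout and batch
# normalization (minibatch statistics during training, running statistics
# at inference). Training protocol: minibatches of 32, a 20% internal
# validation split, early stopping with patience 20, learning-rate halving
# after a 10-epoch validation plateau, and restoration of the best-epoch
# weights.

relu <- function(z) pmax(z, 0)
sigmoid <- function(z) 1 / (1 + exp(-z))

add_bias <- function(z, b) z + rep(b, each = nrow(z))

bce_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

init_mlp <- function(p_in, hidden, batchnorm) {
  sizes <- c(p_in, hidden, 1L)
  L <- length(sizes) - 1L
  params <- list(W = vector("list", L), b = vector("list", L))
  if (batchnorm) {
    params$gamma <- params$beta <- params$run_mean <- params$run_var <-
      vector("list", L - 1L)
  }
  for (l in seq_len(L)) {
    params$W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1]) *
                              sqrt(2 / sizes[l]), sizes[l], sizes[l + 1])
    params$b[[l]] <- numeric(sizes[l + 1])
    if (batchnorm && l < L) {
      params$gamma[[l]] <- rep(1, sizes[l + 1])
      params$beta[[l]] <- numeric(sizes[l + 1])
      params$run_mean[[l]] <- numeric(sizes[l + 1])
      params$run_var[[l]] <- rep(1, sizes[l + 1])
    }
  }
  params
}

# forward pass; training = TRUE uses minibatch BN stats and samples dropout
mlp_forward <- function(params, x, hidden, dropout = 0, batchnorm = FALSE,
                        training = FALSE, bn_momentum = 0.9) {
  L <- length(params$W)
  cache <- list(a = vector("list", L), bn = vector("list", L),
                mask = vector("list", L))
  a <- x
  eps <- 1e-5
  for (l in seq_len(L - 1L)) {
    cache$a[[l]] <- a
    s <- add_bias(a %*% params$W[[l]], params$b[[l]])
    if (batchnorm) {
      if (training) {
        mu <- colMeans(s)
        v <- colMeans(s^2) - mu^2
        params$run_mean[[l]] <- bn_momentum * params$run_mean[[l]] + (1 - bn_momentum) * mu
        params$run_var[[l]] <- bn_momentum * params$run_var[[l]] + (1 - bn_momentum) * v
      } else {
        mu <- params$run_mean[[l]]
        v <- params$run_var[[l]]
      }
      shat <- (s - rep(mu, each = nrow(s))) / rep(sqrt(v + eps), each = nrow(s))
      cache$bn[[l]] <- list(shat = shat, v = v)
      s <- add_bias(shat * rep(params$gamma[[l]], each = nrow(s)), params$beta[[l]])
    }
    h <- relu(s)
    cache$mask[[l]] <- s > 0
    if (training && dropout > 0) {
      keep <- (matrix(stats::runif(length(h)), nrow(h)) > dropout) / (1 - dropout)
      h <- h * keep
      cache$drop <- c(cache$drop, list(keep))
    }
    a <- h
  }
  cache$a[[L]] <- a
  logits <- add_bias(a %*% params$W[[L]], params$b[[L]])
  list(p = sigmoid(logits), cache = cache, params = params)
}

# backward pass for BCE + sigmoid; returns gradients matching params layout
mlp_backward <- function(params, fw, y, dropout, batchnorm) {
  L <- length(params$W)
  n <- length(y)
  grads <- list(W = vector("list", L), b = vector("list", L))
  if (batchnorm) grads$gamma <- grads$beta <- vector("list", L - 1L)
  delta <- (fw$p - y) / n                     # d loss / d logits
  grads$W[[L]] <- crossprod(fw$cache$a[[L]], delta)
  grads$b[[L]] <- colSums(delta)
  da <- delta %*% t(params$W[[L]])
  drop_i <- if (dropout > 0) length(fw$cache$drop) else 0L
  for (l in rev(seq_len(L - 1L))) {
    if (dropout > 0) {
      da <- da * fw$cache$drop[[drop_i]]
      drop_i <- drop_i - 1L
    }
    ds <- da * fw$cache$mask[[l]]             # through ReLU
    if (batchnorm) {
      bn <- fw$cache$bn[[l]]
      grads$gamma[[l]] <- colSums(ds * bn$shat)
      grads$beta[[l]] <- colSums(ds)
      dshat <- ds * rep(params$gamma[[l]], each = nrow(ds))
      ds <- (dshat - rep(colMeans(dshat), each = nrow(ds)) -
               bn$shat * rep(colMeans(dshat * bn$shat), each = nrow(ds))) /
        rep(sqrt(bn$v + 1e-5), each = nrow(ds))
    }
    grads$W[[l]] <- crossprod(fw$cache$a[[l]], ds)
    grads$b[[l]] <- colSums(ds)
    if (l > 1L) da <- ds %*% t(params$W[[l]])
  }
  grads
}

#' Train a feed-forward neural network classifier
#'
#' @param x numeric matrix or data.frame of features (pre-scaled).
#' @param y binary 0/1 labels.
#' @param hidden integer vector of hidden-layer widths, e.g. `c(100, 50)`.
#' @param dropout dropout rate applied after each hidden activation.
#' @param batchnorm apply batch normalization after each hidden layer.
#' @param lr initial Adam learning rate.
#' @param batch_size minibatch size (default 32).
#' @param max_epochs training-epoch cap.
#' @param patience early-stopping patience on validation loss (epochs).
#' @param lr_patience epochs of validation plateau before halving the
#'   learning rate.
#' @param val_fraction internal validation fraction held out from `x`.
#' @param seed RNG seed (initialization, shuffling, dropout).
#' @return object of class `gdm_mlp`: best-epoch parameters plus training
#'   history.
#' @export
mlp_train <- function(x, y, hidden = c(100, 50), dropout = 0,
                      batchnorm = FALSE, lr = 1e-3, batch_size = 32,
                      max_epochs = 120, patience = 20, lr_patience = 10,
                      val_fraction = 0.2, seed = 42) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  set.seed(seed)
  n <- nrow(x)
  n_val <- max(1L, floor(val_fraction * n))
  val_idx <- sample.int(n, n_val)
  xv <- x[val_idx, , drop = FALSE]; yv <- y[val_idx]
  xt <- x[-val_idx, , drop = FALSE]; yt <- y[-val_idx]

  params <- init_mlp(ncol(x), hidden, batchnorm)
  adam <- list(m = rapply(params, function(p) p * 0, how = "replace"),
               v = rapply(params, function(p) p * 0, how = "replace"), t = 0)
  grad_slots <- if (batchnorm) c("W", "b", "gamma", "beta") else c("W", "b")

  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L; lr_wait <- 0L
  history <- numeric(0)
  nt <- nrow(xt)

  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(nt)
    for (start in seq(1, nt, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, nt)]
      if (length(idx) < 2L) next  # BN needs >1 row; negligible data loss
      fw <- mlp_forward(params, xt[idx, , drop = FALSE], hidden, dropout,
                        batchnorm, training = TRUE)
      params <- fw$params                     # updated BN running stats
      grads <- mlp_backward(params, fw, yt[idx], dropout, batchnorm)
      adam$t <- adam$t + 1
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      for (slot in grad_slots) {
        for (l in seq_along(grads[[slot]])) {
          g <- grads[[slot]][[l]]
          if (is.null(g)) next
          adam$m[[slot]][[l]] <- b1 * adam$m[[slot]][[l]] + (1 - b1) * g
          adam$v[[slot]][[l]] <- b2 * adam$v[[slot]][[l]] + (1 - b2) * g^2
          mhat <- adam$m[[slot]][[l]] / (1 - b1^adam$t)
          vhat <- adam$v[[slot]][[l]] / (1 - b2^adam$t)
          params[[slot]][[l]] <- params[[slot]][[l]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
    }
    val_p <- mlp_forward(params, xv, hidden, 0, batchnorm, training = FALSE)$p
    vloss <- bce_loss(val_p, yv)
    history <- c(history, vloss)
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, params = params, epoch = epoch)
      wait <- 0L; lr_wait <- 0L
    } else {
      wait <- wait + 1L
      lr_wait <- lr_wait + 1L
      if (lr_wait >= lr_patience) {
        lr <- lr * 0.5
        lr_wait <- 0L
      }
      if (wait >= patience) break
    }
  }
  structure(list(params = best$params, hidden = hidden, dropout = dropout,
                 batchnorm = batchnorm, best_epoch = best$epoch,
                 val_loss = best$loss, history = history, seed = seed),
            class = "gdm_mlp")
}

#' Predicted positive-class probabilities from a trained network
#'
#' @param object a `gdm_mlp`.
#' @param x feature matrix on the training scale.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.gdm_mlp <- function(object, x, ...) {
  fw <- mlp_forward(object$params, as.matrix(x), object$hidden, 0,
                    object$batchnorm, training = FALSE)
  as.numeric(fw$p)
}
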