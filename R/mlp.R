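#' Fit a small feed-forward neural network classifier
#'
#' A multilayer perceptron with two hidden ReLU layers (64 and 32 units by
#' default) and a softmax output, trained by full-batch Adam on the
#' cross-entropy loss. Written in plain matrix algebra so the hidden-layer
#' architecture is not limited to one layer, fully deterministic given the
#' seed.
#'
#' @param x Numeric matrix, observations x features (pre-standardised by the
#'   caller if desired).
#' @param y Factor (or coercible) of class labels, 2 or more levels.
#' @param hidden Integer vector of hidden-layer sizes.
#' @param epochs Number of full-batch Adam steps.
#' @param learning_rate Adam step size.
#' @param l2 L2 weight-decay coefficient.
#' @param seed Integer seed for the weight initialisation.
#' @return An object of class `invbase_mlp` with a `predict()` method.
#' @export
mlp_fit <- function(x, y, hidden = c(64L, 32L), epochs = 300L,
                    learning_rate = 1e-2, l2 = 1e-4, seed = 0L) {
  x <- as.matrix(x)
  y <- as.factor(y)
  levels_y <- levels(y)
  n_class <- length(levels_y)
  if (n_class < 2L) abort_validation("mlp_fit needs at least two classes")
  yi <- as.integer(y)
  n <- nrow(x)
  sizes <- c(ncol(x), hidden, n_class)
  n_layers <- length(sizes) - 1L

  init <- withr::with_seed(seed, {
    lapply(seq_len(n_layers), function(l) {
      list(
        W = matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                sd = sqrt(2 / sizes[l])),
                   sizes[l], sizes[l + 1L]),
        b = rep(0, sizes[l + 1L])
      )
    })
  })
  W <- lapply(init, `[[`, "W")
  b <- lapply(init, `[[`, "b")

  onehot <- matrix(0, n, n_class)
  onehot[cbind(seq_len(n), yi)] <- 1

  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(bb) bb * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  for (t in seq_len(epochs)) {
    # forward
    a <- vector("list", n_layers + 1L)
    a[[1L]] <- x
    for (l in seq_len(n_layers)) {
      z <- sweep(a[[l]] %*% W[[l]], 2L, b[[l]], `+`)
      a[[l + 1L]] <- if (l < n_layers) pmax(z, 0) else z
    }
    logits <- a[[n_layers + 1L]]
    logits <- logits - apply(logits, 1L, max)
    p <- exp(logits); p <- p / rowSums(p)

    # backward
    delta <- (p - onehot) / n
    gW <- vector("list", n_layers); gb <- vector("list", n_layers)
    for (l in rev(seq_len(n_layers))) {
      gW[[l]] <- crossprod(a[[l]], delta) + l2 * W[[l]]
      gb[[l]] <- colSums(delta)
      if (l > 1L) {
        delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
      }
    }

    # Adam update
    for (l in seq_len(n_layers)) {
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
      c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
      W[[l]] <- W[[l]] - learning_rate * (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + eps)
      b[[l]] <- b[[l]] - learning_rate * (mb[[l]] / c1) / (sqrt(vb[[l]] / c2) + eps)
    }
  }

  structure(
    list(W = W, b = b, levels = levels_y, hidden = hidden,
         epochs = epochs, learning_rate = learning_rate, l2 = l2, seed = seed),
    class = "invbase_mlp"
  )
}

#' Predict class labels from a fitted MLP
#'
#' @param object An `invbase_mlp` from [mlp_fit()].
#' @param newdata Numeric matrix, observations x features.
#' @param ... Unused.
#' @return Factor of predicted labels with the training levels.
#' @export
predict.invbase_mlp <- function(object, newdata, ...) {
  a <- as.matrix(newdata)
  n_layers <- length(object$W)
  for (l in seq_len(n_layers)) {
    z <- sweep(a %*% object$W[[l]], 2L, object$b[[l]], `+`)
    a <- if (l < n_layers) pmax(z, 0) else z
  }
  factor(object$levels[max.col(a, ties.method = "first")],
         levels = object$levels)
}
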