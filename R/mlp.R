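# Feedforward network for beat classification: 75 inputs, six hidden
# layers of 70/60/45/30/20/10 ReLU units, 4 softmax outputs, trained by
# minibatch backpropagation of the categorical cross-entropy with Adam.

.softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Number of trainable parameters of a layered network
#'
#' @param layer_sizes Integer vector of layer widths, input first.
#' @return Total count of weights plus biases.
#' @export
mlp_n_params <- function(layer_sizes) {
  n <- length(layer_sizes)
  as.integer(sum(layer_sizes[-n] * layer_sizes[-1L] + layer_sizes[-1L]))
}

#' Train the feedforward neural-network classifier
#'
#' Hidden layers use ReLU activations; the output layer is softmax over
#' the classes and the loss is the categorical cross-entropy. Weights are
#' initialized with He-scaled Gaussians and updated by minibatch Adam for
#' a fixed number of epochs (50 by default). Training is reproducible
#' given `seed`.
#'
#' @param features Numeric training matrix, one observation per row.
#' @param labels Class labels, one per row; every class should be present.
#' @param hidden Hidden-layer widths.
#' @param epochs Number of passes over the training data.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size (beta1 = 0.9, beta2 = 0.999,
#'   epsilon = 1e-8).
#' @param seed Integer seed for initialization and batch shuffling.
#' @return An object of class `mlp_model` with the fitted weights, the
#'   layer sizes and the per-epoch mean training loss.
#' @export
mlp_train <- function(features, labels, hidden = c(70, 60, 45, 30, 20, 10),
                      epochs = 50L, batch_size = 256L, learning_rate = 1e-3,
                      seed = 1L) {
  features <- as.matrix(features)
  labels <- as.factor(labels)
  n <- nrow(features)
  if (n == 0L) {
    stop("empty training set")
  }
  if (length(labels) != n) {
    stop("`labels` must have one entry per training row")
  }
  lev <- levels(labels)
  sizes <- c(ncol(features), hidden, length(lev))
  n_layers <- length(sizes) - 1L

  restore <- .with_seed_state(seed)
  on.exit(restore(), add = TRUE)

  w <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    w[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                     nrow = sizes[l])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  mw <- lapply(w, function(x) x * 0); vw <- mw
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  y <- diag(length(lev))[as.integer(labels), , drop = FALSE]

  step <- 0L
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    batch_loss <- 0
    starts <- seq(1L, n, by = batch_size)
    for (s in starts) {
      idx <- perm[s:min(s + batch_size - 1L, n)]
      xb <- features[idx, , drop = FALSE]
      yb <- y[idx, , drop = FALSE]
      m <- nrow(xb)

      acts <- vector("list", n_layers + 1L)
      acts[[1L]] <- xb
      for (l in seq_len(n_layers)) {
        z <- acts[[l]] %*% w[[l]] + rep(b[[l]], each = m)
        acts[[l + 1L]] <- if (l < n_layers) pmax(z, 0) else .softmax_rows(z)
      }
      p <- acts[[n_layers + 1L]]
      loss <- -mean(log(pmax(rowSums(p * yb), 1e-300)))
      if (!is.finite(loss)) {
        stop("training diverged: non-finite loss at epoch ", ep)
      }
      batch_loss <- batch_loss + loss * m

      delta <- (p - yb) / m
      for (l in rev(seq_len(n_layers))) {
        gw <- crossprod(acts[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- (delta %*% t(w[[l]])) * (acts[[l]] > 0)
        }
        step_l <- step + 1L
        mw[[l]] <- beta1 * mw[[l]] + (1 - beta1) * gw
        vw[[l]] <- beta2 * vw[[l]] + (1 - beta2) * gw^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhat <- mw[[l]] / (1 - beta1^step_l)
        vhat <- vw[[l]] / (1 - beta2^step_l)
        w[[l]] <- w[[l]] - learning_rate * mhat / (sqrt(vhat) + eps)
        mhatb <- mb[[l]] / (1 - beta1^step_l)
        vhatb <- vb[[l]] / (1 - beta2^step_l)
        b[[l]] <- b[[l]] - learning_rate * mhatb / (sqrt(vhatb) + eps)
      }
      step <- step + 1L
    }
    losses[ep] <- batch_loss / n
  }

  structure(list(weights = w, biases = b, layer_sizes = sizes,
                 classes = lev, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 loss = losses),
            class = "mlp_model")
}

#' Predict with the feedforward network
#'
#' @param model A [mlp_train()] result.
#' @param features Numeric matrix of query rows (or a single vector).
#' @return A list with `labels` (factor, argmax of the softmax),
#'   `posterior` (queries x classes softmax matrix, rows sum to 1) and
#'   `confidence` (max posterior per query).
#' @export
mlp_predict <- function(model, features) {
  stopifnot(inherits(model, "mlp_model"))
  if (!is.matrix(features)) {
    features <- matrix(features, nrow = 1L)
  }
  if (ncol(features) != model$layer_sizes[1L]) {
    stop("feature dimensionality ", ncol(features),
         " does not match the network input size ", model$layer_sizes[1L])
  }
  a <- features
  n_layers <- length(model$weights)
  for (l in seq_len(n_layers)) {
    z <- a %*% model$weights[[l]] + rep(model$biases[[l]], each = nrow(a))
    a <- if (l < n_layers) pmax(z, 0) else .softmax_rows(z)
  }
  colnames(a) <- model$classes
  idx <- max.col(a, ties.method = "first")
  list(labels = factor(model$classes[idx], levels = model$classes),
       posterior = a,
       confidence = a[cbind(seq_len(nrow(a)), idx)])
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("mlp_model: layers %s (%d parameters), %d epochs, final loss %.4f\n",
              paste(x$layer_sizes, collapse = "-"),
              mlp_n_params(x$layer_sizes), x$epochs,
              x$loss[length(x$loss)]))
  invisible(x)
}
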