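#' Fit a probabilistic neural network (Parzen-window classifier)
#'
#' A PNN stores every training observation as a pattern unit. At prediction
#' time, each class's score is a Parzen density estimate — the mean over
#' the class's pattern units of a Gaussian kernel of width `spread` — and
#' the Bayes rule assigns the class with the highest posterior. The layer
#' structure is input / pattern / summation / output with
#' `n_features / n_train / n_classes / 1` units.
#'
#' @param features Numeric training matrix, one observation per row.
#' @param labels Class labels, one per row.
#' @param spread Gaussian kernel width sigma (> 0). The scores use
#'   `exp(-||x - x_i||^2 / (2 * spread^2))`. The default 0.01 is applied to
#'   features on their raw scattering scale.
#' @return An object of class `pnn_model`.
#' @export
pnn_fit <- function(features, labels, spread = 0.01) {
  features <- as.matrix(features)
  if (nrow(features) == 0L) {
    stop("empty training set")
  }
  labels <- as.factor(labels)
  if (length(labels) != nrow(features)) {
    stop("`labels` must have one entry per training row")
  }
  if (spread <= 0) {
    stop("`spread` must be positive")
  }
  structure(list(features = features, labels = labels, spread = spread,
                 layer_sizes = c(input = ncol(features),
                                 pattern = nrow(features),
                                 summation = nlevels(labels),
                                 output = 1L)),
            class = "pnn_model")
}

#' Predict with a probabilistic neural network
#'
#' Class score = mean Gaussian kernel over the class's pattern units;
#' posterior = scores normalized to sum to 1; label = argmax posterior.
#' When every kernel value underflows to zero (queries far from all
#' pattern units relative to `spread`), the class of the nearest pattern
#' unit is used and a warning is emitted; its posterior row is split
#' uniformly over the nearest-distance classes.
#'
#' @param model A [pnn_fit()] result.
#' @param queries Numeric matrix of query rows (or a single vector).
#' @return A list with `labels` (factor), `posterior` (queries x classes
#'   matrix, rows sum to 1) and `confidence` (max posterior per query).
#' @export
pnn_predict <- function(model, queries) {
  stopifnot(inherits(model, "pnn_model"))
  if (!is.matrix(queries)) {
    queries <- matrix(queries, nrow = 1L)
  }
  if (ncol(queries) != ncol(model$features)) {
    stop("query dimensionality ", ncol(queries),
         " does not match training dimensionality ", ncol(model$features))
  }
  lev <- levels(model$labels)
  d2 <- .cross_dist2(queries, model$features)
  kern <- exp(-d2 / (2 * model$spread^2))
  class_mat <- matrix(vapply(lev, function(l) as.numeric(model$labels == l),
                             numeric(nrow(model$features))),
                      ncol = length(lev))
  scores <- (kern %*% class_mat) / rep(colSums(class_mat), each = nrow(queries))
  colnames(scores) <- lev

  tot <- rowSums(scores)
  dead <- tot <= 0 | !is.finite(tot)
  if (any(dead)) {
    warning(sum(dead), " query/queries had numerically zero density; ",
            "falling back to the nearest pattern unit")
    for (i in which(dead)) {
      dmin <- min(d2[i, ])
      near_classes <- unique(as.character(model$labels[d2[i, ] <= dmin + 1e-12]))
      scores[i, ] <- as.numeric(lev %in% near_classes)
    }
    tot <- rowSums(scores)
  }
  posterior <- scores / tot
  idx <- max.col(posterior, ties.method = "first")
  list(labels = factor(lev[idx], levels = lev),
       posterior = posterior,
       confidence = posterior[cbind(seq_len(nrow(posterior)), idx)])
}

#' @export
print.pnn_model <- function(x, ...) {
  cat(sprintf("pnn_model: spread = %g, layers %s\n", x$spread,
              paste(x$layer_sizes, collapse = "/")))
  invisible(x)
}
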