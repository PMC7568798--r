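# Squared Euclidean distances between the rows of two matrices (n x d,
# m x d) -> n x m, via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2 a.b.
.cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Fit a k-nearest-neighbour classifier
#'
#' KNN with Euclidean distance; `k = 4` is the default working point for
#' scattering features of heartbeats.
#'
#' @param features Numeric training matrix, one observation per row.
#' @param labels Class labels, one per row.
#' @param k Number of neighbours (>= 1, <= number of training rows).
#' @return An object of class `knn_model`.
#' @export
knn_fit <- function(features, labels, k = 4L) {
  features <- as.matrix(features)
  if (nrow(features) == 0L) {
    stop("empty training set")
  }
  labels <- as.factor(labels)
  if (length(labels) != nrow(features)) {
    stop("`labels` must have one entry per training row")
  }
  if (k < 1L || k > nrow(features)) {
    stop("`k` must be between 1 and the training-set size")
  }
  structure(list(features = features, labels = labels, k = as.integer(k)),
            class = "knn_model")
}

#' Predict with a k-nearest-neighbour model
#'
#' Each query is assigned the most frequent label among its `k` nearest
#' training observations. A tie between classes is broken in favour of the
#' class of the single nearest neighbour among the tied classes. The mean
#' distance to the `k` neighbours is returned as a (negative-oriented)
#' confidence for vote aggregation.
#'
#' @param model A [knn_fit()] result.
#' @param queries Numeric matrix of query rows (or a single vector).
#' @return A list with `labels` (factor) and `confidence` (numeric,
#'   negative mean neighbour distance — larger is more confident).
#' @export
knn_predict <- function(model, queries) {
  stopifnot(inherits(model, "knn_model"))
  if (!is.matrix(queries)) {
    queries <- matrix(queries, nrow = 1L)
  }
  if (ncol(queries) != ncol(model$features)) {
    stop("query dimensionality ", ncol(queries),
         " does not match training dimensionality ", ncol(model$features))
  }
  k <- model$k
  lev <- levels(model$labels)
  out <- character(nrow(queries))
  conf <- numeric(nrow(queries))
  d2 <- .cross_dist2(queries, model$features)
  for (i in seq_len(nrow(queries))) {
    nn <- order(d2[i, ])[seq_len(k)]
    nn_lab <- model$labels[nn]
    votes <- table(nn_lab)
    best <- names(votes)[votes == max(votes)]
    if (length(best) > 1L) {
      # nearest neighbour among the tied classes decides
      best <- as.character(nn_lab[match(TRUE, as.character(nn_lab) %in% best)])
    }
    out[i] <- best
    conf[i] <- -mean(sqrt(d2[i, nn]))
  }
  list(labels = factor(out, levels = lev), confidence = conf)
}

#' @export
print.knn_model <- function(x, ...) {
  cat(sprintf("knn_model: k = %d, %d training points, %d features\n",
              x$k, nrow(x$features), ncol(x$features)))
  invisible(x)
}
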