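# Reducers that turn a scattering batch (paths x windows x beats) into a
# classifier-ready feature matrix. All of them preserve beat order, never
# read labels to compute features, and record the source beat of every row
# so per-beat majority voting can aggregate window-level predictions.

.check_batch <- function(batch) {
  stopifnot(inherits(batch, "scattering_batch"))
  if (is.null(batch$labels)) {
    stop("the scattering batch carries no labels")
  }
  invisible(batch)
}

.feature_matrix <- function(features, labels, beat_index, window_index) {
  colnames(features) <- sprintf("path%03d", seq_len(ncol(features)) - 1L)
  structure(
    list(features = features,
         labels = labels,
         beat_index = as.integer(beat_index),
         window_index = as.integer(window_index)),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d rows (%d beats) x %d paths\n",
              nrow(x$features), length(unique(x$beat_index)), ncol(x$features)))
  invisible(x)
}

#' Expand every time window into its own feature row
#'
#' Reshapes a `paths x windows x beats` scattering batch into a
#' `(beats * windows) x paths` matrix: one row per (beat, window), rows of
#' one beat contiguous in window order, each row inheriting the beat's
#' label. This is the layout in which every time window is classified
#' separately and the per-window decisions are aggregated by majority vote.
#'
#' @param batch A labelled [transform_batch()] result.
#' @return A `feature_matrix` object: `features`, `labels`, `beat_index`
#'   (source beat per row, 1-based), `window_index` (0-based).
#' @export
expand_window_rows <- function(batch) {
  .check_batch(batch)
  d <- dim(batch$coefficients)
  features <- matrix(aperm(batch$coefficients, c(2L, 3L, 1L)),
                     nrow = d[2L] * d[3L])
  .feature_matrix(features,
                  labels = rep(batch$labels, each = d[2L]),
                  beat_index = rep(seq_len(d[3L]), each = d[2L]),
                  window_index = rep(seq_len(d[2L]) - 1L, times = d[3L]))
}

#' Select a single time window as the feature vector
#'
#' Keeps one scattering time window per beat, giving one `paths`-long
#' feature row per beat. Window indices are 0-based: the "4th time window"
#' in 1-based table numbering is `window_index = 3`.
#'
#' @param batch A labelled [transform_batch()] result.
#' @param window_index 0-based window index.
#' @return A `feature_matrix` with one row per beat.
#' @export
select_window <- function(batch, window_index) {
  .check_batch(batch)
  d <- dim(batch$coefficients)
  if (length(window_index) != 1L || window_index < 0L || window_index >= d[2L]) {
    stop("`window_index` must be a single 0-based index below ", d[2L])
  }
  features <- t(batch$coefficients[, window_index + 1L, , drop = TRUE])
  if (d[3L] == 1L) features <- matrix(features, nrow = 1L)
  .feature_matrix(features,
                  labels = batch$labels,
                  beat_index = seq_len(d[3L]),
                  window_index = rep(as.integer(window_index), d[3L]))
}

#' Select a subset of time windows
#'
#' Keeps the listed windows, one feature row per (beat, selected window),
#' rows of one beat contiguous; beat indices are recorded for majority
#' voting.
#'
#' @param batch A labelled [transform_batch()] result.
#' @param window_indices Distinct 0-based window indices.
#' @return A `feature_matrix` with `length(window_indices)` rows per beat.
#' @export
select_window_subset <- function(batch, window_indices) {
  .check_batch(batch)
  d <- dim(batch$coefficients)
  window_indices <- as.integer(window_indices)
  if (anyDuplicated(window_indices)) {
    stop("`window_indices` must be distinct")
  }
  if (any(window_indices < 0L | window_indices >= d[2L])) {
    stop("`window_indices` must be 0-based indices below ", d[2L])
  }
  k <- length(window_indices)
  sub <- batch$coefficients[, window_indices + 1L, , drop = FALSE]
  features <- matrix(aperm(sub, c(2L, 3L, 1L)), nrow = k * d[3L])
  .feature_matrix(features,
                  labels = rep(batch$labels, each = k),
                  beat_index = rep(seq_len(d[3L]), each = k),
                  window_index = rep(window_indices, times = d[3L]))
}

#' Per-node first principal component of the time windows
#'
#' For each scattering path ("node") independently, the time windows are
#' treated as variables and the beats as observations: the windows are
#' centred by the fitting-set mean, the leading eigenvector of the
#' `windows x windows` covariance is computed, and every beat's windows are
#' projected onto it. The result is one score per node per beat — a
#' `paths`-dimensional feature vector summarizing the temporal profile of
#' each node. Eigenvector signs are fixed so the largest-magnitude loading
#' is positive. Contribution rates (eigenvalue fractions) are returned per
#' node.
#'
#' The component can be fitted on a subset of beats (e.g. the training
#' folds) and applied to all; by default it is fitted on all beats.
#'
#' @param batch A labelled [transform_batch()] result.
#' @param fit_on Integer vector of beat indices used to fit the components
#'   (default: all beats). At least 2.
#' @return A `feature_matrix` with one row per beat, plus
#'   `contribution_rates` (`paths x windows` matrix of eigenvalue
#'   fractions) and `rotation` (`windows x paths` leading eigenvectors).
#' @export
per_node_pc1 <- function(batch, fit_on = NULL) {
  .check_batch(batch)
  d <- dim(batch$coefficients)
  n_paths <- d[1L]; n_win <- d[2L]; n_beats <- d[3L]
  if (is.null(fit_on)) {
    fit_on <- seq_len(n_beats)
  }
  if (length(fit_on) < 2L) {
    stop("need at least 2 fitting observations")
  }
  scores <- matrix(0, nrow = n_beats, ncol = n_paths)
  rates <- matrix(0, nrow = n_paths, ncol = n_win)
  rotation <- matrix(0, nrow = n_win, ncol = n_paths)
  zero_var <- logical(n_paths)
  for (p in seq_len(n_paths)) {
    x <- t(batch$coefficients[p, , , drop = TRUE])   # beats x windows
    if (n_win == 1L) x <- matrix(x, ncol = 1L)
    mu <- colMeans(x[fit_on, , drop = FALSE])
    cv <- stats::cov(x[fit_on, , drop = FALSE])
    tot <- sum(diag(cv))
    if (tot < .Machine$double.eps) {
      zero_var[p] <- TRUE
      rates[p, 1L] <- 1
      next
    }
    eg <- eigen(cv, symmetric = TRUE)
    v <- eg$vectors[, 1L]
    if (v[which.max(abs(v))] < 0) v <- -v
    rotation[, p] <- v
    rates[p, ] <- pmax(eg$values, 0) / sum(pmax(eg$values, 0))
    scores[, p] <- sweep(x, 2L, mu) %*% v
  }
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance node(s); their scores are 0")
  }
  out <- .feature_matrix(scores,
                         labels = batch$labels,
                         beat_index = seq_len(n_beats),
                         window_index = rep(NA_integer_, n_beats))
  out$contribution_rates <- rates
  out$rotation <- rotation
  out
}

#' Write a feature matrix as CSV (plus JSON sidecar for PC1 rates)
#'
#' @param fm A `feature_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(beat = fm$beat_index - 1L,
                   window = fm$window_index,
                   label = as.character(fm$labels),
                   fm$features, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(fm$contribution_rates)) {
    jsonlite::write_json(list(contribution_rates = fm$contribution_rates),
                         paste0(path, ".pc1.json"), digits = NA)
  }
  invisible(path)
}
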