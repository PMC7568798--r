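# Symmetric (reflection) padding of the columns of a matrix to n_pad rows.
.reflect_pad <- function(x, n_pad, pad_left) {
  len <- nrow(x)
  pad_right <- n_pad - len - pad_left
  stopifnot(pad_left <= len, pad_right <= len)
  top <- if (pad_left > 0) x[pad_left:1, , drop = FALSE] else x[0, , drop = FALSE]
  bottom <- if (pad_right > 0) x[len:(len - pad_right + 1), , drop = FALSE] else x[0, , drop = FALSE]
  rbind(top, x, bottom)
}

.ifft <- function(z) stats::mvfft(z, inverse = TRUE) / nrow(z)

# Low-pass filter the columns of a frequency-domain matrix and sample the
# result on the window grid. Returns windows x n.
.lowpass_windows <- function(freq_mat, bank) {
  y <- Mod(.ifft(freq_mat * bank$phi))
  y[bank$window_pos + 1L, , drop = FALSE]
}

# Core cascade on a signal_length x n matrix of signals.
# Returns a paths x windows x n array.
.scatter_matrix <- function(x, bank) {
  cfg <- bank$config
  n <- ncol(x)
  xp <- .reflect_pad(x, bank$n_pad, bank$pad_left)
  X <- stats::mvfft(xp)

  paths <- bank$paths
  out <- array(0, dim = c(nrow(paths), bank$n_windows, n))

  out[1L, , ] <- .lowpass_windows(X, bank)

  if (cfg$max_order >= 1L) {
    psi1 <- bank$layers[[1L]]$filters
    row1 <- which(paths$order == 1L)
    for (j1 in seq_len(ncol(psi1))) {
      u1 <- Mod(.ifft(X * psi1[, j1]))
      f1 <- stats::mvfft(u1)
      out[row1[j1], , ] <- .lowpass_windows(f1, bank)
      if (cfg$max_order >= 2L) {
        psi2 <- bank$layers[[2L]]$filters
        rows2 <- which(paths$order == 2L & paths$j1 == j1)
        for (r in rows2) {
          u2 <- Mod(.ifft(f1 * psi2[, paths$j2[r]]))
          out[r, , ] <- .lowpass_windows(stats::mvfft(u2), bank)
        }
      }
    }
  }
  out
}

#' Wavelet scattering transform of a 1-D signal
#'
#' Computes zeroth-, first- and second-order scattering coefficients of a
#' real signal: the signal is reflection-padded to the next power of two,
#' convolved with the analytic Morlet wavelets of each layer with a complex
#' modulus after every convolution, averaged by the Gaussian low-pass
#' `phi`, and critically downsampled on the window grid determined by the
#' low-pass bandwidth. Second-order coefficients are computed only along
#' frequency-decreasing paths. No logarithm or renormalization is applied
#' to the coefficients.
#'
#' @param signal Real numeric vector of length `config$signal_length`.
#' @param bank A [build_filter_banks()] result (or a [scattering_config()],
#'   in which case the bank is built on the fly).
#' @return An object of class `scattering_tensor`: a list with
#'   `coefficients` (paths x windows matrix of nonnegative values),
#'   `path_table`, `window_times` and `config`.
#' @examples
#' bank <- build_filter_banks(scattering_config())
#' s <- scattering_transform(sin(2 * pi * 10 * (0:249) / 360), bank)
#' dim(s$coefficients) # 75 x 8
#' @export
scattering_transform <- function(signal, bank) {
  if (inherits(bank, "scattering_config")) {
    bank <- build_filter_banks(bank)
  }
  stopifnot(inherits(bank, "scattering_filterbank"))
  if (!is.numeric(signal)) {
    stop("`signal` must be numeric")
  }
  if (length(signal) != bank$config$signal_length) {
    stop("signal length ", length(signal), " does not match the configured length ",
         bank$config$signal_length)
  }
  if (anyNA(signal) || any(!is.finite(signal))) {
    stop("`signal` contains NA or non-finite values")
  }
  coef <- .scatter_matrix(matrix(signal, ncol = 1L), bank)[, , 1L, drop = TRUE]
  structure(
    list(
      coefficients = matrix(coef, nrow = nrow(bank$paths)),
      path_table = bank$paths,
      window_times = bank$window_times,
      config = bank$config
    ),
    class = "scattering_tensor"
  )
}

#' @export
print.scattering_tensor <- function(x, ...) {
  cat(sprintf("Scattering tensor: %d paths x %d windows\n",
              nrow(x$coefficients), ncol(x$coefficients)))
  tab <- table(x$path_table$order)
  cat(sprintf("  %s\n", paste(sprintf("order %s: %d paths", names(tab), tab),
                              collapse = ", ")))
  invisible(x)
}

#' Scattering transform of a batch of beats
#'
#' Applies [scattering_transform()] to every beat of a [beat_set()] (or to
#' the rows of a numeric matrix) and stacks the per-beat tensors, in input
#' order, into a single `paths x windows x beats` array — the tensor layout
#' in which each slice holds the scattering coefficients of one heartbeat.
#'
#' @param beats A [beat_set()] or a numeric matrix with one beat per row.
#' @param bank A [build_filter_banks()] result or a [scattering_config()].
#' @param block_size Number of beats transformed per FFT block (memory
#'   knob; the result does not depend on it).
#' @return An object of class `scattering_batch`: a list with
#'   `coefficients` (paths x windows x beats array), `path_table`,
#'   `window_times`, `config` and `labels` (factor, or `NULL` for a bare
#'   matrix input).
#' @export
transform_batch <- function(beats, bank, block_size = 2048L) {
  if (inherits(bank, "scattering_config")) {
    bank <- build_filter_banks(bank)
  }
  stopifnot(inherits(bank, "scattering_filterbank"))
  labels <- NULL
  if (inherits(beats, "beat_set")) {
    labels <- beats$meta$label
    beats <- beats$samples
  }
  if (!is.matrix(beats) || !is.numeric(beats)) {
    stop("`beats` must be a beat_set or a numeric matrix (one beat per row)")
  }
  if (nrow(beats) == 0L) {
    stop("empty batch")
  }
  if (ncol(beats) != bank$config$signal_length) {
    stop("beat length ", ncol(beats), " does not match the configured length ",
         bank$config$signal_length)
  }
  if (anyNA(beats) || any(!is.finite(beats))) {
    stop("`beats` contains NA or non-finite values")
  }
  n <- nrow(beats)
  out <- array(0, dim = c(nrow(bank$paths), bank$n_windows, n))
  starts <- seq(1L, n, by = block_size)
  for (s in starts) {
    idx <- s:min(s + block_size - 1L, n)
    out[, , idx] <- .scatter_matrix(t(beats[idx, , drop = FALSE]), bank)
  }
  structure(
    list(
      coefficients = out,
      path_table = bank$paths,
      window_times = bank$window_times,
      config = bank$config,
      labels = labels
    ),
    class = "scattering_batch"
  )
}

#' @export
print.scattering_batch <- function(x, ...) {
  d <- dim(x$coefficients)
  cat(sprintf("Scattering batch: %d paths x %d windows x %d beats\n",
              d[1], d[2], d[3]))
  if (!is.null(x$labels)) {
    print(table(x$labels))
  }
  invisible(x)
}

#' Persist a scattering batch as CSV plus a JSON path table
#'
#' Writes the coefficients as a CSV with one row per (beat, window) — beat
#' index, window index, label, then one column per path — and the path
#' table and window times as a JSON sidecar (`<path>.paths.json`).
#'
#' @param batch A [transform_batch()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scattering_batch <- function(batch, path) {
  stopifnot(inherits(batch, "scattering_batch"))
  d <- dim(batch$coefficients)
  flat <- matrix(aperm(batch$coefficients, c(2L, 3L, 1L)), nrow = d[2] * d[3])
  colnames(flat) <- sprintf("path%03d", seq_len(d[1]) - 1L)
  df <- data.frame(
    beat = rep(seq_len(d[3]), each = d[2]) - 1L,
    window = rep(seq_len(d[2]), times = d[3]) - 1L,
    label = if (is.null(batch$labels)) NA_character_
            else as.character(rep(batch$labels, each = d[2])),
    flat,
    check.names = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- list(
    path_table = batch$path_table,
    window_times = batch$window_times,
    config = unclass(batch$config)
  )
  jsonlite::write_json(sidecar, paste0(path, ".paths.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
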