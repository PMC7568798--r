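#' Configuration for the 1-D wavelet scattering network
#'
#' Collects the parameters that determine the scattering architecture: the
#' sampling rate of the input, the invariance scale `T` (time support of the
#' Gaussian low-pass filter, in seconds), the number of wavelets per octave
#' in each filter-bank layer, the maximal scattering order, the expected
#' signal length and an oversampling factor for the output time grid.
#'
#' The default values reproduce the architecture used throughout this
#' package for 360 Hz heartbeats: `T = 0.5` s, `Q = c(8, 1)`, two orders,
#' 250-sample beats. Under that configuration the network has 75 scattering
#' paths and critical downsampling yields 8 time windows per path.
#'
#' @param sampling_rate Sampling rate of the input signal in Hz.
#' @param invariance_scale Invariance scale `T` in seconds. Features are
#'   locally invariant to translations up to roughly this scale. Must not
#'   exceed the signal duration.
#' @param q_factors Integer vector of wavelets per octave, one entry per
#'   scattering layer (length `max_order`). Each entry must be >= 1.
#' @param max_order Maximal scattering order (depth of the cascade); the
#'   default 2 captures essentially all signal energy for this class of
#'   signals.
#' @param signal_length Expected input length in samples.
#' @param oversampling Nonnegative integer log2 oversampling factor for the
#'   output time grid; 0 (the default) is critical downsampling.
#' @return An object of class `scattering_config`.
#' @examples
#' cfg <- scattering_config()
#' cfg
#' @export
scattering_config <- function(sampling_rate = 360,
                              invariance_scale = 0.5,
                              q_factors = c(8, 1),
                              max_order = 2,
                              signal_length = 250,
                              oversampling = 0) {
  stopifnot(is.numeric(sampling_rate), length(sampling_rate) == 1L, sampling_rate > 0)
  stopifnot(is.numeric(invariance_scale), length(invariance_scale) == 1L, invariance_scale > 0)
  stopifnot(is.numeric(signal_length), length(signal_length) == 1L, signal_length >= 2)
  if (max_order < 1) {
    stop("`max_order` must be at least 1")
  }
  if (length(q_factors) != max_order) {
    stop("`q_factors` must have one entry per layer (", max_order, ")")
  }
  if (any(q_factors < 1)) {
    stop("every Q factor must be >= 1")
  }
  if (invariance_scale * sampling_rate > signal_length) {
    stop("invariance scale (", invariance_scale * sampling_rate,
         " samples) exceeds the signal length (", signal_length, " samples)")
  }
  if (oversampling < 0 || oversampling != round(oversampling)) {
    stop("`oversampling` must be a nonnegative integer")
  }
  structure(
    list(
      sampling_rate = as.numeric(sampling_rate),
      invariance_scale = as.numeric(invariance_scale),
      q_factors = as.numeric(q_factors),
      max_order = as.integer(max_order),
      signal_length = as.integer(signal_length),
      oversampling = as.integer(oversampling)
    ),
    class = "scattering_config"
  )
}

#' @export
print.scattering_config <- function(x, ...) {
  cat("Wavelet scattering configuration\n")
  cat(sprintf("  sampling rate   : %g Hz\n", x$sampling_rate))
  cat(sprintf("  invariance scale: %g s (%g samples)\n",
              x$invariance_scale, x$invariance_scale * x$sampling_rate))
  cat(sprintf("  Q factors       : %s\n", paste(x$q_factors, collapse = ", ")))
  cat(sprintf("  max order       : %d\n", x$max_order))
  cat(sprintf("  signal length   : %d samples\n", x$signal_length))
  cat(sprintf("  oversampling    : %d\n", x$oversampling))
  invisible(x)
}

#' Read or write a scattering configuration as JSON
#'
#' @param path Path of the JSON file.
#' @return `read_scattering_config()` returns a [scattering_config()] object;
#'   `write_scattering_config()` returns `path` invisibly.
#' @export
read_scattering_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scattering_config(
    sampling_rate = x$sampling_rate,
    invariance_scale = x$invariance_scale,
    q_factors = x$q_factors,
    max_order = x$max_order,
    signal_length = x$signal_length,
    oversampling = if (is.null(x$oversampling)) 0 else x$oversampling
  )
}

#' @rdname read_scattering_config
#' @param config A [scattering_config()] object.
#' @export
write_scattering_config <- function(config, path) {
  stopifnot(inherits(config, "scattering_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
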