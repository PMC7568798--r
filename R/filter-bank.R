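# Filter-bank design constants, frozen for the default architecture.
#
# .SIGMA0: frequency-domain standard deviation of the Gaussian low-pass,
#   in units of 1/T. The value 2*sqrt(2*log(2))/(2*pi) makes the time-domain
#   full width at half maximum of phi equal to the invariance scale T, which
#   is the sense in which T is the "time support" of the low-pass filter.
# .R_PSI: amplitude at which adjacent geometric-regime wavelets cross;
#   sqrt(1/2) is half-power overlap.
# .LIN_SPACING: spacing of the fixed-bandwidth (linear-regime) wavelets as a
#   fraction of their full half-power bandwidth; below 1 the low-frequency
#   filters overlap more densely than the geometric ones.
.SIGMA0 <- sqrt(2 * log(2)) / pi
.R_PSI <- sqrt(0.5)
.LIN_SPACING <- 0.6

# Periodized Gaussian on the normalized frequency circle [0, 1).
.gauss_periodized <- function(w, center, sigma) {
  g <- 0
  for (m in -1:1) {
    g <- g + exp(-((w - center + m)^2) / (2 * sigma^2))
  }
  g
}

# Frequency response of a zero-mean analytic Morlet (Gabor) wavelet:
# a Gaussian bump at `xi` minus a scaled Gaussian at DC. The correction
# factor is computed from the periodized responses so the DC bin vanishes
# exactly on the discrete frequency circle.
.morlet_hat <- function(n, xi, sigma) {
  w <- (seq_len(n) - 1) / n
  kappa <- .gauss_periodized(0, xi, sigma) / .gauss_periodized(0, 0, sigma)
  .gauss_periodized(w, xi, sigma) - kappa * .gauss_periodized(w, 0, sigma)
}

# Center frequencies and bandwidths of one filter-bank layer (normalized
# frequency, cycles/sample). Geometric (constant-Q) spacing from just below
# Nyquist down to where the constant-Q bandwidth would drop below
# `sigma_min`; optionally continued with fixed-bandwidth, linearly spaced
# filters down to `sigma_min` itself.
.design_layer <- function(q, sigma_min, linear = TRUE) {
  xi_max <- max(1 / (1 + 2^(3 / q)), 0.35)
  slope <- (2^(1 / q) - 1) / (2^(1 / q) + 1) / sqrt(2 * log(1 / .R_PSI))
  xis <- numeric(0)
  sigmas <- numeric(0)
  xi <- xi_max
  while (slope * xi >= sigma_min) {
    xis <- c(xis, xi)
    sigmas <- c(sigmas, slope * xi)
    xi <- xi / 2^(1 / q)
  }
  if (!length(xis)) {
    stop("invariance scale too short: no constant-Q wavelets fit above the low-pass bandwidth")
  }
  if (linear) {
    step <- .LIN_SPACING * 2 * sqrt(2 * log(2)) * sigma_min
    xi <- xis[length(xis)] - step
    while (xi >= sigma_min) {
      xis <- c(xis, xi)
      sigmas <- c(sigmas, sigma_min)
      xi <- xi - step
    }
  }
  list(xi = xis, sigma = sigmas)
}

# Scale a layer's wavelets by a common factor so that the Littlewood-Paley
# sum |phi|^2 + (1/2) sum_j (|psi_j(w)|^2 + |psi_j(-w)|^2) is bounded by 1,
# with equality attained somewhere on the covered band.
.lp_normalize <- function(filters, phi) {
  n <- length(phi)
  pos <- 2:(n %/% 2 + 1)
  neg <- n - pos + 2
  p_sum <- rowSums(filters^2)
  p_pos <- 0.5 * (p_sum[pos] + p_sum[neg])
  head_room <- pmax(1 - phi[pos]^2, 0)
  ok <- p_pos > 1e-6
  filters * sqrt(min(head_room[ok] / p_pos[ok]))
}

#' Build the Gabor wavelet filter banks of a scattering network
#'
#' Constructs the Gaussian low-pass filter `phi` and one analytic Morlet
#' (Gabor) band-pass filter bank per scattering layer, all sampled in the
#' frequency domain at the padded signal resolution. Within each layer the
#' filters are constant-Q (geometrically spaced, `Q` per octave) from just
#' below the Nyquist frequency down to the invariance-scale bandwidth, and
#' the first layer is continued with fixed-bandwidth, linearly spaced
#' filters so that frequencies down to `1/T` remain covered. Each wavelet is
#' exactly zero-mean, and each layer is normalized so its Littlewood-Paley
#' sum is bounded by 1.
#'
#' @param config A [scattering_config()] object.
#' @return An object of class `scattering_filterbank` with elements
#'   `config`, `n_pad` (FFT length), `pad_left`, `hop` (output hop in
#'   samples), `n_windows`, `window_times` (0-based window-center sample
#'   positions in the unpadded signal), `phi` (real frequency response),
#'   `layers` (per layer: `xi`, `sigma` in cycles/sample, Hz equivalents,
#'   and a `filters` matrix with one column per wavelet), and `paths`
#'   (data frame of scattering paths: `order`, `j1`, `j2`).
#' @examples
#' bank <- build_filter_banks(scattering_config())
#' nrow(bank$paths) # 75 for the default architecture
#' @export
build_filter_banks <- function(config) {
  stopifnot(inherits(config, "scattering_config"))
  t_samp <- config$invariance_scale * config$sampling_rate
  n_pad <- 2^ceiling(log2(config$signal_length))
  pad_left <- (n_pad - config$signal_length) %/% 2L
  sigma_phi <- .SIGMA0 / t_samp

  hop <- 2^max(floor(log2(t_samp)) - 2 - config$oversampling, 0)
  hop <- min(hop, n_pad)
  n_windows <- n_pad %/% hop
  window_pos <- (seq_len(n_windows) - 1L) * hop + hop %/% 2L # 0-based, padded
  window_times <- window_pos - pad_left                       # 0-based, unpadded

  w <- (seq_len(n_pad) - 1) / n_pad
  phi <- .gauss_periodized(w, 0, sigma_phi)

  layers <- vector("list", config$max_order)
  for (k in seq_len(config$max_order)) {
    d <- .design_layer(config$q_factors[k], sigma_phi, linear = (k == 1L))
    filt <- vapply(seq_along(d$xi),
                   function(i) .morlet_hat(n_pad, d$xi[i], d$sigma[i]),
                   numeric(n_pad))
    filt <- .lp_normalize(filt, phi)
    layers[[k]] <- list(
      xi = d$xi,
      sigma = d$sigma,
      center_frequencies = d$xi * config$sampling_rate,
      bandwidths = d$sigma * sqrt(2 * log(2)) * config$sampling_rate,
      filters = filt
    )
  }

  paths <- data.frame(order = 0L, j1 = NA_integer_, j2 = NA_integer_)
  if (config$max_order >= 1L) {
    paths <- rbind(paths, data.frame(order = 1L,
                                     j1 = seq_along(layers[[1L]]$xi),
                                     j2 = NA_integer_))
  }
  if (config$max_order >= 2L) {
    # frequency-decreasing rule: keep (j1, j2) only when the center
    # frequency of psi_j2 lies below the half-power bandwidth of psi_j1
    bw1 <- layers[[1L]]$sigma * sqrt(2 * log(2))
    for (j1 in seq_along(layers[[1L]]$xi)) {
      j2 <- which(layers[[2L]]$xi < bw1[j1])
      if (length(j2)) {
        paths <- rbind(paths, data.frame(order = 2L, j1 = j1, j2 = j2))
      }
    }
  }
  rownames(paths) <- NULL

  structure(
    list(
      config = config,
      n_pad = as.integer(n_pad),
      pad_left = as.integer(pad_left),
      hop = as.integer(hop),
      n_windows = as.integer(n_windows),
      window_pos = as.integer(window_pos),
      window_times = as.integer(window_times),
      sigma_phi = sigma_phi,
      phi = phi,
      layers = layers,
      paths = paths
    ),
    class = "scattering_filterbank"
  )
}

#' @export
print.scattering_filterbank <- function(x, ...) {
  cat("Scattering filter bank\n")
  cat(sprintf("  FFT length %d, hop %d -> %d time windows\n",
              x$n_pad, x$hop, x$n_windows))
  for (k in seq_along(x$layers)) {
    cat(sprintf("  layer %d: %d wavelets, %.2f-%.2f Hz (Q = %g)\n",
                k, length(x$layers[[k]]$xi),
                min(x$layers[[k]]$center_frequencies),
                max(x$layers[[k]]$center_frequencies),
                x$config$q_factors[k]))
  }
  tab <- table(x$paths$order)
  cat(sprintf("  paths: %s (total %d)\n",
              paste(sprintf("order %s: %d", names(tab), tab), collapse = ", "),
              nrow(x$paths)))
  invisible(x)
}

#' Littlewood-Paley sum of a filter-bank layer
#'
#' Evaluates `|phi(w)|^2 + (1/2) * sum_j (|psi_j(w)|^2 + |psi_j(-w)|^2)` on
#' the discrete frequency grid. A sum close to 1 over the covered band means
#' the layer is approximately energy-preserving; a sum bounded by 1
#' guarantees the layer (and hence the scattering transform) is
#' nonexpansive.
#'
#' @param bank A [build_filter_banks()] result.
#' @param layer Layer index (1-based).
#' @return A data frame with `frequency_hz` and `lp_sum` over positive
#'   frequencies up to Nyquist.
#' @export
littlewood_paley_sum <- function(bank, layer = 1L) {
  stopifnot(inherits(bank, "scattering_filterbank"))
  n <- bank$n_pad
  pos <- 2:(n %/% 2 + 1)
  neg <- n - pos + 2
  filt <- bank$layers[[layer]]$filters
  p_sum <- rowSums(filt^2)
  lp <- bank$phi[pos]^2 + 0.5 * (p_sum[pos] + p_sum[neg])
  data.frame(
    frequency_hz = (pos - 1) / n * bank$config$sampling_rate,
    lp_sum = lp
  )
}

#' Time support (FWHM) of the filter-bank envelopes
#'
#' Returns the full width at half maximum of the time-domain Gaussian
#' envelope of each filter, in samples. For a Gaussian with frequency-domain
#' standard deviation `sigma` (cycles/sample) the time-domain standard
#' deviation is `1 / (2 * pi * sigma)`.
#'
#' @param bank A [build_filter_banks()] result.
#' @return A list with `phi` (scalar) and one numeric vector per layer.
#' @export
filter_time_supports <- function(bank) {
  stopifnot(inherits(bank, "scattering_filterbank"))
  fwhm <- function(sigma) 2 * sqrt(2 * log(2)) / (2 * pi * sigma)
  c(list(phi = fwhm(bank$sigma_phi)),
    lapply(bank$layers, function(l) fwhm(l$sigma)))
}
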