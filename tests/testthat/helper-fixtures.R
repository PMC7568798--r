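# Shared fixtures, built in code at test time.

.fixtures <- new.env(parent = emptyenv())

# Default-architecture filter bank, built once per test run.
default_bank <- function() {
  if (is.null(.fixtures$bank)) {
    .fixtures$bank <- build_filter_banks(scattering_config())
  }
  .fixtures$bank
}

# Small toy architecture (64-sample signals) used by the direct-convolution
# oracle; kept small so O(N^2) time-domain convolution stays cheap.
toy_bank <- function() {
  if (is.null(.fixtures$toy_bank)) {
    .fixtures$toy_bank <- build_filter_banks(
      scattering_config(sampling_rate = 64, invariance_scale = 1,
                        q_factors = c(8, 1), signal_length = 64)
    )
  }
  .fixtures$toy_bank
}

# Direct O(N^2) time-domain reimplementation of the scattering cascade:
# circular convolution computed sample by sample from the time-domain
# kernels. Independent of the FFT route used by the package.
direct_scatter <- function(signal, bank) {
  n_pad <- bank$n_pad
  x <- scatbeat:::.reflect_pad(matrix(signal, ncol = 1L), n_pad, bank$pad_left)[, 1L]
  to_time <- function(hat) fft(hat, inverse = TRUE) / n_pad
  circ_conv <- function(a, h) {
    n <- length(a)
    vapply(seq_len(n) - 1L, function(t) {
      sum(a * h[((t - (seq_len(n) - 1L)) %% n) + 1L])
    }, complex(1))
  }
  phi_t <- to_time(bank$phi)
  lowpass <- function(u) Mod(circ_conv(u, phi_t))[bank$window_pos + 1L]

  paths <- bank$paths
  out <- matrix(0, nrow(paths), bank$n_windows)
  out[1L, ] <- lowpass(x)
  psi1_t <- lapply(seq_len(ncol(bank$layers[[1]]$filters)),
                   function(j) to_time(bank$layers[[1]]$filters[, j]))
  psi2_t <- if (length(bank$layers) >= 2L) {
    lapply(seq_len(ncol(bank$layers[[2]]$filters)),
           function(j) to_time(bank$layers[[2]]$filters[, j]))
  }
  for (j1 in seq_along(psi1_t)) {
    u1 <- Mod(circ_conv(x, psi1_t[[j1]]))
    out[which(paths$order == 1L)[j1], ] <- lowpass(u1)
    for (r in which(paths$order == 2L & paths$j1 == j1)) {
      u2 <- Mod(circ_conv(u1, psi2_t[[paths$j2[r]]]))
      out[r, ] <- lowpass(u2)
    }
  }
  out
}

# Well-separated 4-class Gaussian blobs in `d` dimensions.
make_blobs <- function(n_per_class = 30L, d = 5L, sep = 8, sd = 1, seed = 1L) {
  set.seed(seed)
  classes <- aami_classes()
  centers <- matrix(0, 4L, d)
  for (i in 1:4) centers[i, i] <- sep
  x <- do.call(rbind, lapply(1:4, function(i) {
    matrix(rnorm(n_per_class * d, sd = sd), ncol = d) +
      matrix(centers[i, ], n_per_class, d, byrow = TRUE)
  }))
  list(features = x,
       labels = factor(rep(classes, each = n_per_class), levels = classes))
}

# Published cross-validated confusion matrices used as metric worked
# examples (counts as printed; rows = true class in N, S, V, F order).
published_cm <- function(which) {
  m <- switch(which,
    nn_all_windows = rbind(c(88681, 369, 737, 213),
                           c(4106, 82994, 2006, 894),
                           c(2669, 2132, 83701, 1498),
                           c(2124, 2872, 4843, 80161)),
    nn_w4 = rbind(c(88146, 811, 789, 254),
                  c(3181, 85641, 901, 277),
                  c(1553, 1323, 85084, 2040),
                  c(1108, 2439, 3343, 83110)),
    pnn_w4 = rbind(c(86415, 2540, 615, 430),
                   c(171, 89828, 0, 1),
                   c(1, 71, 89879, 49),
                   c(0, 1701, 1645, 86654)),
    knn_w4 = rbind(c(88915, 644, 281, 160),
                   c(893, 87177, 1155, 775),
                   c(496, 4545, 82247, 2712),
                   c(0, 3, 0, 89997)),
    stop("unknown fixture")
  )
  as_confusion_matrix(m)
}
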