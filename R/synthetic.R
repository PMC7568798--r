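# Synthetic heartbeat generator: each beat is a sum of Gaussian bumps
# (P, Q, R, S, T waves) on a 250-sample, 360 Hz grid with the R wave at
# 0-based sample 99, plus seeded per-component jitter and baseline noise.
# The four class templates are loosely modelled on textbook lead-II
# morphology; they are test fixtures with class-distinct shapes, not
# physiological claims.

.default_templates <- function() {
  mk <- function(class, centers, widths, amps) {
    list(class = class,
         components = data.frame(center = centers, width = widths, amplitude = amps),
         amp_jitter = 0.06,     # relative sd of per-component amplitude jitter
         width_jitter = 0.05,   # relative sd of width jitter
         offset_jitter = 1.5,   # sd of per-component center jitter, samples
         baseline_sd = 0.03)    # sd of additive baseline noise, mV
  }
  list(
    # N: full P-QRS-T
    N = mk("N",
           centers = c(45, 92, 99, 106, 160),
           widths = c(8, 2.2, 3.2, 2.6, 12),
           amps = c(0.15, -0.12, 1.00, -0.22, 0.30)),
    # S: premature supraventricular — shortened pre-R interval, reduced P
    S = mk("S",
           centers = c(72, 92, 99, 106, 150),
           widths = c(5, 2.2, 3.2, 2.6, 11),
           amps = c(0.06, -0.10, 0.95, -0.20, 0.28)),
    # V: ventricular — widened QRS, absent P, inverted T
    V = mk("V",
           centers = c(94, 99, 112, 170),
           widths = c(6.5, 9, 7, 14),
           amps = c(-0.25, 1.05, -0.45, -0.35)),
    # F: fusion — average of the N and V morphologies
    F = mk("F",
           centers = c(45, 93, 99, 109, 165),
           widths = c(8, 4.5, 6, 4.8, 13),
           amps = c(0.07, -0.18, 1.00, -0.33, -0.03))
  )
}

#' Synthetic heartbeat templates
#'
#' Returns the class templates used by [generate_beat()] and
#' [generate_dataset()]: per class, a set of Gaussian components (center
#' offset in samples, width in samples, amplitude in mV) for the P/Q/R/S/T
#' waves, jitter spreads and the baseline noise level. The R component is
#' centred at 0-based sample 99 of a 250-sample beat. Edit the returned
#' list to change the morphology.
#'
#' @return Named list of templates (`N`, `S`, `V`, `F`).
#' @export
beat_templates <- function() .default_templates()

#' Noise-free mean waveform of a template
#'
#' @param template One entry of [beat_templates()].
#' @param n_samples Beat length in samples.
#' @return Numeric vector of length `n_samples`.
#' @export
template_waveform <- function(template, n_samples = 250L) {
  t <- seq_len(n_samples) - 1L
  y <- numeric(n_samples)
  comp <- template$components
  for (i in seq_len(nrow(comp))) {
    y <- y + comp$amplitude[i] *
      exp(-(t - comp$center[i])^2 / (2 * comp$width[i]^2))
  }
  y
}

#' Generate one synthetic heartbeat
#'
#' Draws a beat from a template: each Gaussian component's amplitude,
#' width and center are jittered (seeded), the components are summed on a
#' 250-sample 360 Hz grid, and white baseline noise is added.
#' Reproducible given the seed.
#'
#' @param template One entry of [beat_templates()].
#' @param seed Integer seed.
#' @param n_samples Beat length in samples.
#' @return A [beat_set()] holding the single labelled beat.
#' @export
generate_beat <- function(template, seed = 1L, n_samples = 250L) {
  restore <- .with_seed_state(seed)
  on.exit(restore(), add = TRUE)
  comp <- template$components
  t <- seq_len(n_samples) - 1L
  y <- numeric(n_samples)
  for (i in seq_len(nrow(comp))) {
    amp <- comp$amplitude[i] * (1 + stats::rnorm(1, sd = template$amp_jitter))
    wid <- comp$width[i] * exp(stats::rnorm(1, sd = template$width_jitter))
    ctr <- comp$center[i] + stats::rnorm(1, sd = template$offset_jitter)
    y <- y + amp * exp(-(t - ctr)^2 / (2 * wid^2))
  }
  y <- y + stats::rnorm(n_samples, sd = template$baseline_sd)
  beat_set(matrix(y, nrow = 1L), label = template$class,
           record_id = "synthetic", r_index = 99L, augmented = FALSE)
}

#' Generate a balanced synthetic beat dataset
#'
#' Produces `n_per_class` beats for each of the four AAMI classes from the
#' default templates and shuffles them with the seed. Beat-to-beat
#' variation comes from the per-component jitter and baseline noise of the
#' templates.
#'
#' @param n_per_class Beats per class (>= 1).
#' @param seed Integer seed.
#' @param templates Template list, by default [beat_templates()].
#' @param n_samples Beat length in samples.
#' @return A [beat_set()] with `4 * n_per_class` shuffled beats.
#' @export
generate_dataset <- function(n_per_class, seed = 1L,
                             templates = beat_templates(),
                             n_samples = 250L) {
  stopifnot(n_per_class >= 1L)
  restore <- .with_seed_state(seed)
  on.exit(restore(), add = TRUE)
  sets <- lapply(templates, function(tm) {
    samples <- matrix(0, nrow = n_per_class, ncol = n_samples)
    t <- seq_len(n_samples) - 1L
    comp <- tm$components
    for (b in seq_len(n_per_class)) {
      y <- numeric(n_samples)
      for (i in seq_len(nrow(comp))) {
        amp <- comp$amplitude[i] * (1 + stats::rnorm(1, sd = tm$amp_jitter))
        wid <- comp$width[i] * exp(stats::rnorm(1, sd = tm$width_jitter))
        ctr <- comp$center[i] + stats::rnorm(1, sd = tm$offset_jitter)
        y <- y + amp * exp(-(t - ctr)^2 / (2 * wid^2))
      }
      samples[b, ] <- y + stats::rnorm(n_samples, sd = tm$baseline_sd)
    }
    beat_set(samples, label = rep(tm$class, n_per_class),
             record_id = "synthetic", r_index = 99L, augmented = FALSE)
  })
  all <- do.call(c, sets)
  all[sample.int(length(all))]
}

#' Write a small synthetic WFDB record
#'
#' Builds a two-lead record by concatenating synthetic beats at regular
#' R-R intervals (MLII as the second lead, to exercise channel selection)
#' and writes the `.hea`/`.dat`/`.atr` files with beat annotations at the
#' R-peaks, so the WFDB readers can be tested offline.
#'
#' @param dir Output directory.
#' @param record Record name.
#' @param labels Beat labels in record order (AAMI beat symbols accepted
#'   by [map_annotation_symbol()], e.g. `c("N", "V", "N")`).
#' @param seed Integer seed.
#' @param rr Samples between consecutive R-peaks.
#' @param sampling_rate Sampling rate written to the header.
#' @param format WFDB signal format (212 or 16).
#' @return The record prefix path, invisibly.
#' @export
write_synthetic_wfdb <- function(dir, record = "synth", labels = c("N", "V", "N", "S", "N"),
                                 seed = 1L, rr = 300L, sampling_rate = 360,
                                 format = 212L) {
  restore <- .with_seed_state(seed)
  on.exit(restore(), add = TRUE)
  templates <- beat_templates()
  classes <- as.character(map_annotation_symbol(labels))
  n <- length(labels)
  len <- (n + 1L) * rr
  mlii <- stats::rnorm(len, sd = 0.01)
  r_peaks <- rr * seq_len(n)                 # 0-based R-peak positions
  for (i in seq_len(n)) {
    tm <- templates[[if (classes[i] == "Q") "N" else classes[i]]]
    wave <- template_waveform(tm)
    idx <- (r_peaks[i] - 99L):(r_peaks[i] + 150L) + 1L
    mlii[idx] <- mlii[idx] + wave
  }
  other <- 0.5 * mlii + stats::rnorm(len, sd = 0.01)
  ann <- data.frame(sample = r_peaks, symbol = labels)
  write_wfdb_record(dir, record,
                    signals = cbind(V5 = other, MLII = mlii),
                    sampling_rate = sampling_rate,
                    descriptions = c("V5", "MLII"),
                    annotations = ann, format = format)
}
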