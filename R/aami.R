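#' AAMI EC57 heartbeat classes
#'
#' The ANSI/AAMI EC57:1998 standard groups the MIT-BIH beat annotation
#' vocabulary into five classes: nonectopic (N), supraventricular ectopic
#' (S), ventricular ectopic (V), fusion (F) and unknown/paced (Q).
#' `aami_classes()` returns the four classes retained for classification
#' (Q is discarded upstream); `aami_classes(all = TRUE)` includes Q.
#'
#' @param all If `TRUE`, include the discarded class Q.
#' @return Character vector of class codes.
#' @export
aami_classes <- function(all = FALSE) {
  if (all) c("N", "S", "V", "F", "Q") else c("N", "S", "V", "F")
}

# One editable table mapping WFDB beat annotation codes to AAMI classes.
# `code` is the numeric annotation type stored in WFDB annotation files,
# `symbol` the single-character display form, `name` the long form.
.AAMI_BEAT_TABLE <- data.frame(
  code = c(1L, 2L, 3L, 34L, 11L,
           8L, 4L, 7L, 9L,
           5L, 10L,
           6L,
           12L, 38L, 13L),
  symbol = c("N", "L", "R", "e", "j",
             "A", "a", "J", "S",
             "V", "E",
             "F",
             "/", "f", "Q"),
  name = c("normal", "left bundle branch block beat",
           "right bundle branch block beat", "atrial escape beat",
           "nodal (junctional) escape beat",
           "atrial premature beat", "aberrated atrial premature beat",
           "nodal (junctional) premature beat",
           "supraventricular premature beat",
           "premature ventricular contraction", "ventricular escape beat",
           "fusion of ventricular and normal beat",
           "paced beat", "fusion of paced and normal beat",
           "unclassifiable beat"),
  class = c("N", "N", "N", "N", "N",
            "S", "S", "S", "S",
            "V", "V",
            "F",
            "Q", "Q", "Q"),
  stringsAsFactors = FALSE
)

#' Map a beat annotation symbol to its AAMI class
#'
#' Accepts the standard single-character WFDB beat codes (`"N"`, `"L"`,
#' `"R"`, `"e"`, `"j"`, `"A"`, `"a"`, `"J"`, `"S"`, `"V"`, `"E"`, `"F"`,
#' `"/"`, `"f"`, `"Q"`), the long annotation names (case-insensitive, e.g.
#' `"premature ventricular contraction"`), or the numeric WFDB annotation
#' codes. Non-beat annotations are not part of the vocabulary and must be
#' filtered out before mapping.
#'
#' @param symbol Character or integer vector of beat annotations.
#' @return Factor of AAMI classes with levels `N, S, V, F, Q`.
#' @examples
#' map_annotation_symbol(c("V", "L", "/"))
#' map_annotation_symbol("premature ventricular contraction")
#' @export
map_annotation_symbol <- function(symbol) {
  tab <- .AAMI_BEAT_TABLE
  if (is.numeric(symbol)) {
    idx <- match(as.integer(symbol), tab$code)
  } else {
    symbol <- as.character(symbol)
    idx <- match(symbol, tab$symbol)
    long <- match(tolower(trimws(symbol)), tab$name)
    # allow names with or without a trailing "beat"
    long2 <- match(paste(tolower(trimws(symbol)), "beat"), tab$name)
    idx[is.na(idx)] <- long[is.na(idx)]
    idx[is.na(idx)] <- long2[is.na(idx)]
  }
  if (anyNA(idx)) {
    bad <- unique(symbol[is.na(idx)])
    stop("unknown beat annotation symbol(s): ", paste(bad, collapse = ", "))
  }
  factor(tab$class[idx], levels = aami_classes(all = TRUE))
}

#' The beat-symbol vocabulary and its AAMI grouping
#'
#' @return Data frame with columns `code` (numeric WFDB annotation type),
#'   `symbol`, `name` and `class`.
#' @export
aami_beat_table <- function() .AAMI_BEAT_TABLE

#' Segment fixed-length beats around annotated R-peaks
#'
#' Extracts one window per R-peak, `pre` samples before the peak and `post`
#' samples after it (250 samples with the defaults, R-peak at 0-based
#' offset 99). Beats whose window would cross a record boundary are
#' dropped, as are beats labelled Q. Input order is preserved.
#'
#' @param signal Numeric vector, the ECG lead in mV.
#' @param r_peaks Strictly increasing integer vector of 0-based R-peak
#'   sample indices.
#' @param labels AAMI classes for each peak (anything accepted by
#'   [map_annotation_symbol()] levels `N,S,V,F,Q`).
#' @param pre,post Samples kept before/after the R-peak.
#' @param record_id Record identifier stored in the result.
#' @return A [beat_set()] of the kept beats.
#' @examples
#' x <- sin(2 * pi * (0:299) / 50)
#' segment_beats(x, r_peaks = c(99L, 120L), labels = c("N", "Q"))
#' @export
segment_beats <- function(signal, r_peaks, labels, pre = 99L, post = 150L,
                          record_id = NA_character_) {
  stopifnot(is.numeric(signal))
  r_peaks <- as.integer(r_peaks)
  if (is.unsorted(r_peaks, strictly = TRUE)) {
    stop("`r_peaks` must be strictly increasing")
  }
  if (length(r_peaks) != length(labels)) {
    stop("`labels` must have one entry per R-peak")
  }
  labels <- factor(as.character(labels), levels = aami_classes(all = TRUE))
  if (anyNA(labels)) {
    stop("labels must be AAMI classes N, S, V, F or Q")
  }
  n <- length(signal)
  keep <- (r_peaks - pre >= 0L) & (r_peaks + post <= n - 1L) & labels != "Q"
  r_keep <- r_peaks[keep]
  width <- pre + post + 1L
  samples <- matrix(0, nrow = length(r_keep), ncol = width)
  for (i in seq_along(r_keep)) {
    samples[i, ] <- signal[(r_keep[i] - pre + 1L):(r_keep[i] + post + 1L)]
  }
  beat_set(samples,
           label = droplevels(labels[keep], exclude = "Q"),
           record_id = record_id,
           r_index = r_keep,
           augmented = FALSE)
}

#' Balance classes by random subsampling and Gaussian-noise augmentation
#'
#' Classes with at least `target_per_class` beats are randomly subsampled
#' to the target without adding noise. Classes below the target keep all
#' their original beats and are topped up with noisy copies — a uniformly
#' resampled original plus white Gaussian noise with zero mean and
#' `noise_variance` variance (in squared signal units, mV^2), independent
#' per sample — until the target is reached. Augmented copies are flagged.
#' With the default target of 90000 applied to the full four-class MIT-BIH
#' beat inventory this produces 360000 beats.
#'
#' @param beats A [beat_set()] containing every class at least once.
#' @param target_per_class Target beat count per class.
#' @param noise_variance Variance of the additive Gaussian noise.
#' @param seed Integer seed; the result is reproducible given the seed.
#' @return A balanced [beat_set()].
#' @export
augment_to_balance <- function(beats, target_per_class = 90000L,
                               noise_variance = 0.05, seed = 1L) {
  stopifnot(inherits(beats, "beat_set"))
  if (target_per_class <= 0) {
    stop("`target_per_class` must be positive")
  }
  counts <- table(beats$meta$label)
  if (any(counts == 0)) {
    stop("every class must be present; missing: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  }
  rng <- .with_seed_state(seed)
  on.exit(rng(), add = TRUE)

  pieces <- lapply(aami_classes(), function(cl) {
    idx <- which(beats$meta$label == cl)
    n <- length(idx)
    if (n >= target_per_class) {
      keep <- if (n == target_per_class) idx else sort(sample(idx, target_per_class))
      beats[keep]
    } else {
      extra <- idx[sample.int(n, target_per_class - n, replace = TRUE)]
      noisy <- beats[extra]
      noisy$samples <- noisy$samples +
        matrix(stats::rnorm(length(noisy$samples), mean = 0,
                            sd = sqrt(noise_variance)),
               nrow = nrow(noisy$samples))
      noisy$meta$augmented <- TRUE
      c(beats[idx], noisy)
    }
  })
  do.call(c, pieces)
}

# Set the RNG to a reproducible state and return a restorer.
.with_seed_state <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
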