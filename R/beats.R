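#' Container for a set of segmented heartbeats
#'
#' A `beat_set` stores beats as a numeric matrix (one row per beat, one
#' column per sample, in mV) together with per-beat metadata: the AAMI
#' class label, the source record, the R-peak sample index in that record,
#' and whether the beat is a noise-augmented copy.
#'
#' @param samples Numeric matrix, one beat per row.
#' @param label Factor or character vector of AAMI classes (`N`, `S`, `V`,
#'   `F`), one per beat.
#' @param record_id Character vector of source record identifiers.
#' @param r_index Integer vector of R-peak sample indices (0-based) in the
#'   source record.
#' @param augmented Logical vector; `TRUE` for noise-augmented copies.
#' @return An object of class `beat_set` with elements `samples` (matrix)
#'   and `meta` (data frame with `label`, `record_id`, `r_index`,
#'   `augmented`).
#' @export
beat_set <- function(samples, label,
                     record_id = NA_character_,
                     r_index = NA_integer_,
                     augmented = FALSE) {
  if (!is.matrix(samples)) {
    samples <- matrix(samples, nrow = 1L)
  }
  n <- nrow(samples)
  label <- factor(as.character(label), levels = aami_classes())
  if (anyNA(label)) {
    stop("labels must be AAMI classes: ", paste(aami_classes(), collapse = ", "))
  }
  if (length(label) != n) {
    stop("`label` must have one entry per beat")
  }
  meta <- data.frame(
    label = label,
    record_id = rep_len(as.character(record_id), n),
    r_index = rep_len(as.integer(r_index), n),
    augmented = rep_len(as.logical(augmented), n)
  )
  structure(list(samples = samples, meta = meta), class = "beat_set")
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("beat_set: %d beats x %d samples\n", nrow(x$samples), ncol(x$samples)))
  print(table(x$meta$label))
  if (any(x$meta$augmented)) {
    cat(sprintf("  %d augmented copies\n", sum(x$meta$augmented)))
  }
  invisible(x)
}

#' @export
length.beat_set <- function(x) nrow(x$samples)

#' Subset a beat set
#'
#' @param x A [beat_set()].
#' @param i Beat indices (any form accepted by matrix row indexing).
#' @param ... Ignored.
#' @return A [beat_set()] with the selected beats.
#' @export
`[.beat_set` <- function(x, i, ...) {
  structure(list(samples = x$samples[i, , drop = FALSE],
                 meta = x$meta[i, , drop = FALSE]),
            class = "beat_set")
}

#' Concatenate beat sets
#'
#' @param ... [beat_set()] objects with equal beat lengths.
#' @return The combined [beat_set()].
#' @export
c.beat_set <- function(...) {
  sets <- list(...)
  stopifnot(all(vapply(sets, inherits, logical(1), "beat_set")))
  structure(list(samples = do.call(rbind, lapply(sets, `[[`, "samples")),
                 meta = do.call(rbind, lapply(sets, `[[`, "meta"))),
            class = "beat_set")
}

#' Read and write beats as CSV
#'
#' The interchange format has one row per beat: the sample columns
#' (`s000`, `s001`, ...), then `label`, `record_id`, `r_index`,
#' `augmented`.
#'
#' @param beats A [beat_set()].
#' @param path CSV file path.
#' @return `write_beats_csv()` returns `path` invisibly;
#'   `read_beats_csv()` returns a [beat_set()].
#' @export
write_beats_csv <- function(beats, path) {
  stopifnot(inherits(beats, "beat_set"))
  m <- beats$samples
  colnames(m) <- sprintf("s%03d", seq_len(ncol(m)) - 1L)
  df <- data.frame(m, beats$meta, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beats_csv
#' @export
read_beats_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  sample_cols <- grep("^s[0-9]+$", names(df))
  beat_set(
    samples = as.matrix(df[, sample_cols, drop = FALSE]),
    label = df$label,
    record_id = df$record_id,
    r_index = df$r_index,
    augmented = df$augmented
  )
}
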