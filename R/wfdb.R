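# Minimal WFDB i/o: header (.hea) text parser, signal (.dat) reader for
# formats 212 and 16, and the MIT binary annotation (.atr) format. Covers
# the subset of the spec used by the MIT-BIH Arrhythmia Database plus a
# writer so synthetic fixtures can exercise the reader offline.

# annotation type codes with special meaning in the .atr byte stream
.ATR_SKIP <- 59L
.ATR_NUM <- 60L
.ATR_SUB <- 61L
.ATR_CHN <- 62L
.ATR_AUX <- 63L

#' Read a WFDB header file
#'
#' @param path Path to the `.hea` file (or the record prefix without
#'   extension).
#' @return A list with `record`, `n_signals`, `sampling_rate`, `n_samples`
#'   and a `signals` data frame (`file`, `format`, `gain`, `baseline`,
#'   `units`, `adc_zero`, `description`).
#' @export
read_wfdb_header <- function(path) {
  if (!grepl("\\.hea$", path)) {
    path <- paste0(path, ".hea")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  head_tok <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  record <- sub("/.*$", "", head_tok[1L])
  n_sig <- as.integer(head_tok[2L])
  fs <- if (length(head_tok) >= 3L) as.numeric(sub("/.*$", "", head_tok[3L])) else 250
  n_samp <- if (length(head_tok) >= 4L) as.integer(head_tok[4L]) else NA_integer_

  sig <- lapply(lines[1L + seq_len(n_sig)], function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    fmt <- as.integer(sub("[x:+].*$", "", tok[2L]))
    gain_spec <- if (length(tok) >= 3L) tok[3L] else "200"
    units <- if (grepl("/", gain_spec)) sub("^.*/", "", gain_spec) else "mV"
    gain_num <- sub("/.*$", "", gain_spec)
    baseline <- NA_integer_
    if (grepl("\\(", gain_num)) {
      baseline <- as.integer(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_num))
      gain_num <- sub("\\(.*$", "", gain_num)
    }
    gain <- as.numeric(gain_num)
    if (is.na(gain) || gain == 0) gain <- 200
    adc_zero <- if (length(tok) >= 5L) as.integer(tok[5L]) else 0L
    if (is.na(baseline)) baseline <- adc_zero
    desc <- if (length(tok) >= 9L) paste(tok[9:length(tok)], collapse = " ") else ""
    data.frame(file = tok[1L], format = fmt, gain = gain, baseline = baseline,
               units = units, adc_zero = adc_zero, description = desc,
               stringsAsFactors = FALSE)
  })
  list(record = record,
       n_signals = n_sig,
       sampling_rate = fs,
       n_samples = n_samp,
       signals = do.call(rbind, sig))
}

# decode format-212 bytes (3 bytes -> 2 twelve-bit two's-complement samples)
.decode_212 <- function(bytes) {
  nb <- length(bytes) - length(bytes) %% 3L
  b <- matrix(as.integer(bytes[seq_len(nb)]), nrow = 3L)
  s1 <- bitwAnd(b[2L, ], 0x0FL) * 256L + b[1L, ]
  s2 <- bitwAnd(b[2L, ], 0xF0L) * 16L + b[3L, ]
  out <- as.vector(rbind(s1, s2))
  out[out >= 2048L] <- out[out >= 2048L] - 4096L
  out
}

.encode_212 <- function(samples) {
  if (length(samples) %% 2L == 1L) {
    samples <- c(samples, 0L)
  }
  s <- as.integer(samples)
  if (any(s < -2048L | s > 2047L)) {
    stop("format 212 samples must fit in 12 bits")
  }
  s[s < 0L] <- s[s < 0L] + 4096L
  s1 <- s[seq(1L, length(s), 2L)]
  s2 <- s[seq(2L, length(s), 2L)]
  rbind(
    bitwAnd(s1, 0xFFL),
    bitwAnd(s1 %/% 256L, 0x0FL) + bitwAnd(s2 %/% 256L, 0x0FL) * 16L,
    bitwAnd(s2, 0xFFL)
  )
}

#' Read a WFDB signal file
#'
#' Supports formats 212 (packed 12-bit pairs, as in the MIT-BIH Arrhythmia
#' Database) and 16 (little-endian 16-bit). Samples are converted to
#' physical units via `(adc - baseline) / gain`.
#'
#' @param path Record prefix (with or without `.hea`).
#' @return Numeric matrix, one column per signal, in physical units (mV);
#'   column names are the header descriptions.
#' @export
read_wfdb_signal <- function(path) {
  hdr <- read_wfdb_header(path)
  dat <- file.path(dirname(path), hdr$signals$file[1L])
  fmt <- hdr$signals$format[1L]
  n_sig <- hdr$n_signals
  raw_bytes <- readBin(dat, "raw", n = file.size(dat))
  adc <- if (fmt == 212L) {
    .decode_212(as.integer(raw_bytes))
  } else if (fmt == 16L) {
    readBin(raw_bytes, "integer", n = length(raw_bytes) %/% 2L,
            size = 2L, signed = TRUE, endian = "little")
  } else {
    stop("unsupported WFDB signal format: ", fmt)
  }
  n_samp <- length(adc) %/% n_sig
  if (!is.na(hdr$n_samples)) {
    n_samp <- min(n_samp, hdr$n_samples)
  }
  adc <- matrix(adc[seq_len(n_samp * n_sig)], ncol = n_sig, byrow = TRUE)
  phys <- sweep(sweep(adc, 2L, hdr$signals$baseline, "-"),
                2L, hdr$signals$gain, "/")
  colnames(phys) <- hdr$signals$description
  phys
}

#' Read a WFDB annotation file
#'
#' Parses the MIT binary annotation format: a stream of 16-bit
#' little-endian words carrying a 6-bit annotation type and a 10-bit time
#' increment, with SKIP/NUM/SUB/CHN/AUX pseudo-annotations handled per the
#' format definition.
#'
#' @param path Path to the annotation file, or the record prefix if
#'   `extension` is given.
#' @param extension Annotation extension (default `"atr"`).
#' @return Data frame with `sample` (0-based annotation sample index),
#'   `code` (numeric annotation type) and `symbol` (display character for
#'   beat codes, `NA` otherwise).
#' @export
read_wfdb_annotation <- function(path, extension = "atr") {
  if (!file.exists(path)) {
    path <- paste0(sub("\\.hea$", "", path), ".", extension)
  }
  bytes <- readBin(path, "raw", n = file.size(path))
  words <- readBin(bytes, "integer", n = length(bytes) %/% 2L,
                   size = 2L, signed = FALSE, endian = "little")
  time <- 0
  i <- 1L
  samples <- integer(0)
  codes <- integer(0)
  pending_skip <- 0
  while (i <= length(words)) {
    a <- words[i] %/% 1024L
    interval <- words[i] %% 1024L
    if (a == 0L && interval == 0L) {
      break
    }
    if (a == .ATR_SKIP) {
      hi <- words[i + 1L]
      lo <- words[i + 2L]
      skip <- hi * 65536 + lo
      if (skip >= 2^31) skip <- skip - 2^32
      pending_skip <- pending_skip + skip
      i <- i + 3L
    } else if (a == .ATR_AUX) {
      i <- i + 1L + (interval + interval %% 2L) %/% 2L
    } else if (a %in% c(.ATR_NUM, .ATR_SUB, .ATR_CHN)) {
      i <- i + 1L
    } else {
      time <- time + interval + pending_skip
      pending_skip <- 0
      samples <- c(samples, time)
      codes <- c(codes, a)
      i <- i + 1L
    }
  }
  tab <- .AAMI_BEAT_TABLE
  data.frame(sample = as.integer(samples),
             code = codes,
             symbol = tab$symbol[match(codes, tab$code)],
             stringsAsFactors = FALSE)
}

#' Write a WFDB record (header, signal, annotations)
#'
#' Emits a `.hea`/`.dat` pair (formats 212 or 16) and optionally a binary
#' annotation file, so that the package's readers can be exercised on
#' synthetic records without external data.
#'
#' @param dir Output directory.
#' @param record Record name.
#' @param signals Numeric matrix in mV, one column per lead.
#' @param sampling_rate Sampling rate in Hz.
#' @param descriptions Lead names, one per column (e.g. `"MLII"`).
#' @param annotations Optional data frame with `sample` (0-based) and
#'   either `code` (numeric annotation type) or `symbol`.
#' @param gain ADC gain (adu/mV).
#' @param format Signal format, 212 or 16.
#' @return The record prefix path, invisibly.
#' @export
write_wfdb_record <- function(dir, record, signals, sampling_rate,
                              descriptions = colnames(signals),
                              annotations = NULL, gain = 200, format = 212L) {
  if (!is.matrix(signals)) {
    signals <- matrix(signals, ncol = 1L)
  }
  n_sig <- ncol(signals)
  if (is.null(descriptions)) {
    descriptions <- sprintf("sig%d", seq_len(n_sig))
  }
  adc <- round(signals * gain)
  dat_name <- paste0(record, ".dat")
  hea <- c(
    sprintf("%s %d %g %d", record, n_sig, sampling_rate, nrow(signals)),
    sprintf("%s %d %g(0)/mV %d 0 0 0 0 %s",
            dat_name, format, gain, if (format == 212L) 12L else 16L,
            descriptions)
  )
  writeLines(hea, file.path(dir, paste0(record, ".hea")))

  interleaved <- as.integer(t(adc))
  con <- file(file.path(dir, dat_name), "wb")
  if (format == 212L) {
    writeBin(as.raw(as.vector(.encode_212(interleaved))), con)
  } else if (format == 16L) {
    writeBin(interleaved, con, size = 2L, endian = "little")
  } else {
    close(con)
    stop("unsupported WFDB signal format: ", format)
  }
  close(con)

  if (!is.null(annotations)) {
    stopifnot(!is.unsorted(annotations$sample))
    codes <- if ("code" %in% names(annotations)) {
      as.integer(annotations$code)
    } else {
      .AAMI_BEAT_TABLE$code[match(annotations$symbol, .AAMI_BEAT_TABLE$symbol)]
    }
    if (anyNA(codes)) {
      stop("annotations contain symbols outside the beat vocabulary")
    }
    words <- integer(0)
    prev <- 0
    for (k in seq_along(codes)) {
      delta <- annotations$sample[k] - prev
      prev <- annotations$sample[k]
      if (delta > 1023) {
        words <- c(words, .ATR_SKIP * 1024L,
                   delta %/% 65536, delta %% 65536)
        delta <- 0
      }
      words <- c(words, codes[k] * 1024L + delta)
    }
    words <- c(words, 0L)
    con <- file(file.path(dir, paste0(record, ".atr")), "wb")
    writeBin(as.integer(words), con, size = 2L, endian = "little")
    close(con)
  }
  invisible(file.path(dir, record))
}

#' Load a WFDB record for beat classification
#'
#' Reads the record, selects the requested lead (modified lead II by
#' default), reads the reference annotations, keeps only beat annotations
#' and maps them to AAMI classes. Records on the paced-record exclusion
#' list are refused with a condition of class `scatbeat_paced_record` so
#' callers can skip them.
#'
#' @param path Record prefix (directory + record name, no extension).
#' @param lead Lead description to select.
#' @param exclude_paced Refuse records on `paced_records`.
#' @param paced_records Record names excluded as paced. The default four
#'   are the AAMI EC57 paced records of the MIT-BIH Arrhythmia Database.
#' @return A list with `signal` (numeric vector, mV), `r_peaks` (0-based
#'   annotation sample indices), `labels` (AAMI factor incl. Q),
#'   `sampling_rate` and `record`.
#' @export
load_wfdb_record <- function(path, lead = "MLII", exclude_paced = TRUE,
                             paced_records = c("102", "104", "107", "217")) {
  hdr <- read_wfdb_header(path)
  if (exclude_paced && hdr$record %in% paced_records) {
    cond <- structure(
      class = c("scatbeat_paced_record", "error", "condition"),
      list(message = paste0("record ", hdr$record,
                            " is on the paced-record exclusion list"),
           call = sys.call())
    )
    stop(cond)
  }
  sig <- read_wfdb_signal(path)
  col <- which(colnames(sig) == lead)
  if (!length(col)) {
    stop("record ", hdr$record, " has no lead '", lead, "' (leads: ",
         paste(colnames(sig), collapse = ", "), ")")
  }
  ann <- read_wfdb_annotation(path)
  is_beat <- ann$code %in% .AAMI_BEAT_TABLE$code
  ann <- ann[is_beat, , drop = FALSE]
  list(signal = sig[, col[1L]],
       r_peaks = ann$sample,
       labels = map_annotation_symbol(ann$code),
       sampling_rate = hdr$sampling_rate,
       record = hdr$record)
}
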