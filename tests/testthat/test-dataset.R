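test_that("the beat-symbol mapping partitions the vocabulary into five classes", {
  tab <- aami_beat_table()
  mapped <- map_annotation_symbol(tab$symbol)
  expect_identical(as.character(mapped), tab$class)
  expect_setequal(unique(tab$class), aami_classes(all = TRUE))
  # long names and numeric codes agree with symbols
  expect_identical(map_annotation_symbol("premature ventricular contraction"),
                   map_annotation_symbol("V"))
  expect_identical(map_annotation_symbol("left bundle branch block beat"),
                   map_annotation_symbol("L"))
  expect_identical(as.character(map_annotation_symbol("paced beat")), "Q")
  expect_identical(map_annotation_symbol(tab$code), mapped)
  expect_error(map_annotation_symbol("Z"), "unknown beat annotation")
})

test_that("segmentation keeps exact 250-sample windows and drops the rest", {
  x <- seq_len(300) / 100
  one <- segment_beats(x, r_peaks = 99L, labels = "N")
  expect_identical(dim(one$samples), c(1L, 250L))
  expect_identical(one$samples[1L, ], x[1:250])        # boundary-exact slice
  expect_identical(one$meta$r_index, 99L)
  # window starting before the record, or running past its end, is dropped
  expect_identical(length(segment_beats(x, 98L, "N")), 0L)
  expect_identical(length(segment_beats(x, 150L, "N")), 0L)
  # Q beats are dropped, order preserved
  got <- segment_beats(x, c(99L, 120L), c("N", "Q"))
  expect_identical(length(got), 1L)
  expect_identical(as.character(got$meta$label), "N")
  got2 <- segment_beats(x, c(99L, 110L, 130L), c("V", "N", "F"))
  expect_identical(as.character(got2$meta$label), c("V", "N", "F"))
  expect_error(segment_beats(x, c(120L, 99L), c("N", "N")), "increasing")
})

test_that("augmentation balances every class exactly at the target", {
  set.seed(2)
  counts <- c(N = 400L, S = 35L, V = 60L, F = 12L)
  beats <- beat_set(matrix(rnorm(sum(counts) * 8L), ncol = 8L),
                    label = rep(names(counts), counts))
  out <- augment_to_balance(beats, target_per_class = 100L, seed = 9L)
  expect_identical(length(out), 400L)
  expect_true(all(table(out$meta$label) == 100L))
  # the oversized class is subsampled without noise; small classes keep
  # all originals bit-exactly and flag their noisy copies
  expect_false(any(out$meta$augmented[out$meta$label == "N"]))
  expect_identical(sum(out$meta$augmented[out$meta$label == "F"]), 88L)
  f_orig <- out$samples[out$meta$label == "F" & !out$meta$augmented, , drop = FALSE]
  expect_identical(f_orig, beats$samples[beats$meta$label == "F", , drop = FALSE])
  # reproducible given the seed
  out2 <- augment_to_balance(beats, target_per_class = 100L, seed = 9L)
  expect_identical(out$samples, out2$samples)
  expect_error(augment_to_balance(beats, target_per_class = 0L), "positive")
})

test_that("classes already at the target pass through untouched", {
  beats <- beat_set(matrix(rnorm(40 * 8), ncol = 8),
                    label = rep(aami_classes(), each = 10L))
  out <- augment_to_balance(beats, target_per_class = 10L, seed = 1L)
  expect_identical(out$samples, beats$samples)
  expect_false(any(out$meta$augmented))
})

test_that("augmentation noise has the stated moments", {
  n_beats <- 250L; len <- 400L                    # 1e5 noise samples
  base <- matrix(rnorm(2 * len), ncol = len)
  beats <- beat_set(rbind(base, matrix(rnorm(3 * len), ncol = len)),
                    label = c("N", "S", "V", "F", "F"))
  out <- augment_to_balance(beats, target_per_class = n_beats,
                            noise_variance = 0.05, seed = 33L)
  aug <- out[out$meta$augmented & out$meta$label == "N"]
  # recover the noise by subtracting the source beat (nearest original)
  src <- beats$samples[beats$meta$label == "N", , drop = FALSE]
  noise <- unlist(lapply(seq_len(nrow(aug$samples)), function(i) {
    diffs <- sweep(src, 2L, aug$samples[i, ])
    aug$samples[i, ] - src[which.min(rowSums(diffs^2)), ]
  }))
  n <- length(noise)
  expect_gte(n, 9e4)
  expect_lt(abs(mean(noise)), 3 * sqrt(0.05 / n))
  expect_lt(abs(var(noise) - 0.05), 3 * 0.05 * sqrt(2 / (n - 1)))
})

test_that("beat sets survive the CSV round trip", {
  beats <- generate_dataset(3L, seed = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_beats_csv(beats, path)
  back <- read_beats_csv(path)
  expect_equal(back$samples, beats$samples, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$meta$label, beats$meta$label)
  expect_identical(back$meta$augmented, beats$meta$augmented)
})
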