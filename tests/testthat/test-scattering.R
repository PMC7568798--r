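test_that("default transform of a 250-sample beat is 75 paths x 8 windows", {
  bank <- default_bank()
  s <- scattering_transform(template_waveform(beat_templates()$N), bank)
  expect_identical(dim(s$coefficients), c(75L, 8L))
  expect_true(all(s$coefficients >= 0))
  expect_identical(s$path_table$order[1L], 0L)
})

test_that("a constant signal excites only the order-0 path", {
  bank <- default_bank()
  s <- scattering_transform(rep(2, 250), bank)
  expect_lt(max(s$coefficients[-1L, ]), 1e-6 * 2)
  # order-0 value = c times the (unit) DC mass of phi
  expect_equal(unname(s$coefficients[1L, ]), rep(2, 8), tolerance = 1e-6)
})

test_that("a pure cosine peaks on the matching first-order path", {
  bank <- default_bank()
  t <- (0:249) / bank$config$sampling_rate
  o1 <- which(bank$paths$order == 1L)
  for (j_star in c(3L, 10L, 25L, 38L)) {
    f <- bank$layers[[1]]$center_frequencies[j_star]
    s <- scattering_transform(cos(2 * pi * f * t), bank)
    expect_identical(which.max(rowMeans(s$coefficients[o1, ])), j_star)
  }
})

test_that("invalid signals are rejected", {
  bank <- default_bank()
  expect_error(scattering_transform(rnorm(100), bank), "length")
  x <- rnorm(250); x[5] <- NA
  expect_error(scattering_transform(x, bank), "NA")
  x[5] <- Inf
  expect_error(scattering_transform(x, bank), "NA|finite")
})

test_that("FFT cascade agrees with direct time-domain convolution", {
  bank <- toy_bank()
  set.seed(11)
  for (rep in 1:3) {
    x <- rnorm(64)
    s_fft <- scattering_transform(x, bank)$coefficients
    s_direct <- direct_scatter(x, bank)
    expect_lt(max(abs(s_fft - s_direct)) / max(abs(s_direct)), 1e-8)
  }
})

test_that("the transform is nonexpansive", {
  bank <- default_bank()
  set.seed(21)
  for (rep in 1:5) {
    f <- rnorm(250)
    g <- f + rnorm(250, sd = runif(1, 0.01, 2))
    sf <- scattering_transform(f, bank)$coefficients
    sg <- scattering_transform(g, bank)$coefficients
    expect_lte(sqrt(sum((sf - sg)^2)), sqrt(sum((f - g)^2)) * (1 + 1e-6))
  }
})

test_that("features are stable to small translations, improving as the shift shrinks", {
  bank <- default_bank()
  beat <- template_waveform(beat_templates()$N)
  s0 <- scattering_transform(beat, bank)$coefficients
  rel <- vapply(c(1L, 2L, 4L, 8L), function(sh) {
    shifted <- c(beat[-seq_len(sh)], beat[seq_len(sh)])
    ss <- scattering_transform(shifted, bank)$coefficients
    sqrt(sum((ss - s0)^2)) / sqrt(sum(s0^2))
  }, numeric(1))
  expect_lt(max(rel), 0.05)
  expect_true(all(diff(rel) > 0))
})

test_that("coefficient energy decreases with scattering order", {
  bank <- default_bank()
  set.seed(31)
  ord <- bank$paths$order
  for (rep in 1:3) {
    f <- rnorm(250)
    s <- scattering_transform(f, bank)$coefficients
    e1 <- sum(s[ord == 1L, ]^2)
    e2 <- sum(s[ord == 2L, ]^2)
    expect_lt(e2, e1)
    expect_lt(e1, sum(f^2))
  }
})

test_that("batch transform matches per-beat transforms and preserves order", {
  bank <- default_bank()
  beats <- generate_dataset(3L, seed = 5)
  batch <- transform_batch(beats, bank)
  expect_identical(dim(batch$coefficients), c(75L, 8L, 12L))
  expect_identical(batch$labels, beats$meta$label)
  for (i in c(1L, 7L, 12L)) {
    single <- scattering_transform(beats$samples[i, ], bank)
    expect_equal(batch$coefficients[, , i], single$coefficients,
                 ignore_attr = TRUE)
  }
  # identical beats give identical slices; block size does not matter
  same <- beat_set(beats$samples[c(1L, 1L, 1L), ], rep("N", 3L))
  b2 <- transform_batch(same, bank, block_size = 2L)
  expect_equal(b2$coefficients[, , 1L], b2$coefficients[, , 3L])
  expect_error(transform_batch(beats$samples[0L, , drop = FALSE], bank), "empty")
})

test_that("oversampling densifies the window grid without changing paths", {
  cfg <- scattering_config(oversampling = 1)
  bank <- build_filter_banks(cfg)
  expect_identical(bank$n_windows, 16L)
  expect_identical(nrow(bank$paths), 75L)
})

test_that("a scattering batch survives the CSV round trip", {
  bank <- default_bank()
  beats <- generate_dataset(2L, seed = 9)
  batch <- transform_batch(beats, bank)
  path <- withr::local_tempfile(fileext = ".csv")
  write_scattering_batch(batch, path)
  df <- read.csv(path, check.names = FALSE)
  expect_identical(nrow(df), 8L * 8L)
  expect_equal(as.numeric(df[1L, -(1:3)]), batch$coefficients[, 1L, 1L],
               tolerance = 1e-12, ignore_attr = TRUE)
  sidecar <- jsonlite::read_json(paste0(path, ".paths.json"), simplifyVector = TRUE)
  expect_identical(nrow(sidecar$path_table), 75L)
})
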