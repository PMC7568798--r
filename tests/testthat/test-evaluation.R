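test_that("stratified folds partition the beats evenly per class", {
  labels <- factor(rep(aami_classes(), each = 1000L), levels = aami_classes())
  folds <- make_folds(labels, n_folds = 10L, seed = 3L)
  expect_identical(sort(unique(folds)), 1:10)
  expect_true(all(table(folds) == 400L))
  expect_true(all(table(labels, folds) == 100L))
  expect_identical(folds, make_folds(labels, n_folds = 10L, seed = 3L))
  expect_false(identical(folds, make_folds(labels, n_folds = 10L, seed = 4L)))
  # 100 beats, 10 folds -> each fold size 10
  small <- factor(rep(aami_classes(), each = 25L), levels = aami_classes())
  expect_true(all(table(make_folds(small, 10L, 1L)) == 10L))
  expect_error(make_folds(factor(c(rep("N", 20), "V")), n_folds = 10L), "at least")
})

test_that("majority vote picks the modal window label, confidence breaks ties", {
  expect_identical(as.character(majority_vote(rep("V", 8L))), "V")
  expect_identical(as.character(majority_vote(c(rep("N", 5L), rep("S", 3L)))), "N")
  # 4 N (summed confidence 2.0) vs 4 V (2.5) -> V
  lab <- c(rep("N", 4L), rep("V", 4L))
  conf <- c(rep(0.5, 4L), rep(0.625, 4L))
  expect_identical(as.character(majority_vote(lab, conf)), "V")
  # grouped by beat, output ordered by beat index
  got <- majority_vote(c("N", "N", "V", "V", "V", "S"),
                       confidence = rep(1, 6L),
                       beat_index = c(2L, 2L, 2L, 1L, 1L, 1L))
  expect_identical(as.character(got), c("V", "N"))
})

test_that("confusion matrices count and reject as specified", {
  truth <- rep(aami_classes(), each = 10L)
  cm <- confusion_matrix(truth, truth)
  expect_identical(unname(diag(cm)), rep(10L, 4L))
  expect_identical(sum(cm), 40L)
  all_n <- confusion_matrix(truth, rep("N", 40L))
  expect_identical(unname(all_n[, 1L]), rep(10L, 4L))
  expect_identical(sum(all_n[, 2:4]), 0L)
  set.seed(13)
  pred <- sample(aami_classes(), 100L, replace = TRUE)
  truth2 <- sample(aami_classes(), 100L, replace = TRUE)
  cm2 <- confusion_matrix(truth2, pred)
  expect_equal(unname(rowSums(cm2)),
               unname(as.vector(table(factor(truth2, aami_classes())))),
               ignore_attr = TRUE)
  expect_error(confusion_matrix(c("N", "X"), c("N", "N")), "outside")
  expect_error(confusion_matrix(c("N"), c("N", "N")), "equal length")
})

test_that("per-class metrics reproduce the published 8-window worked example", {
  cm <- published_cm("nn_all_windows")
  m <- per_class_metrics(cm)
  expect_equal(round(m$ppv, 1), c(90.9, 93.9, 91.7, 96.9))
  expect_equal(round(m$sen, 1), c(98.5, 92.2, 93.0, 89.1))
  # the printed class-F specificity is not reproducible from the printed
  # counts by the one-vs-rest formula; assert the consistent cells only
  expect_equal(round(m$spec[1:3], 1), c(96.7, 98.0, 97.2))
  perfect <- as_confusion_matrix(diag(4L) * 5L)
  mp <- per_class_metrics(perfect)
  expect_true(all(unlist(mp[, -1L]) == 100))
})

test_that("undefined metric denominators give NA, not zero", {
  cm <- as_confusion_matrix(rbind(c(10, 0, 0, 0),
                                  c(0, 0, 0, 0),
                                  c(0, 0, 5, 0),
                                  c(0, 0, 0, 2)))
  m <- per_class_metrics(cm)
  expect_true(is.na(m$ppv[2L]))
  expect_true(is.na(m$sen[2L]))
})

test_that("binary collapse reproduces the published normal-vs-abnormal rows", {
  knn <- binary_collapse_metrics(published_cm("knn_w4"))
  expect_identical(c(knn$tp, knn$tn, knn$fp, knn$fn),
                   c(268611L, 88915L, 1085L, 1389L))
  expect_equal(round(c(knn$acc, knn$ppv, knn$sen, knn$spec), 1),
               c(99.3, 99.6, 99.5, 98.8))
  pnn <- binary_collapse_metrics(published_cm("pnn_w4"))
  expect_identical(c(pnn$tp, pnn$tn, pnn$fp, pnn$fn),
                   c(269828L, 86415L, 3585L, 172L))
  expect_equal(round(c(pnn$acc, pnn$ppv, pnn$sen, pnn$spec), 1),
               c(99.0, 98.7, 99.9, 96.0))
  diagcm <- as_confusion_matrix(diag(4L) * 7L)
  b <- binary_collapse_metrics(diagcm)
  expect_identical(c(b$fp, b$fn), c(0L, 0L))
  expect_equal(b$acc, 100)
  # counts always conserve the beat total
  expect_identical(knn$tp + knn$tn + knn$fp + knn$fn, sum(published_cm("knn_w4")))
})

test_that("per-class sensitivities aggregate to the overall accuracy", {
  for (fx in c("nn_all_windows", "pnn_w4", "knn_w4")) {
    cm <- published_cm(fx)
    m <- per_class_metrics(cm)
    agg <- sum(m$sen * rowSums(cm) / sum(cm))
    expect_equal(agg, overall_accuracy(cm), tolerance = 1e-10)
  }
})

test_that("cross-validated experiments conserve counts and are reproducible", {
  beats <- generate_dataset(30L, seed = 19L)
  ex <- run_experiment(beats, reducer = "window:3", classifier = "knn",
                       n_folds = 5L, seed = 19L)
  # every beat tested exactly once: row sums equal class totals
  expect_equal(unname(rowSums(ex$confusion)), rep(30, 4))
  ex2 <- run_experiment(beats, reducer = "window:3", classifier = "knn",
                        n_folds = 5L, seed = 19L)
  expect_identical(ex$confusion, ex2$confusion)
  expect_identical(ex$per_class, ex2$per_class)
})

test_that("window-expanded features are aggregated by per-beat vote", {
  beats <- generate_dataset(15L, seed = 23L)
  ex <- run_experiment(beats, reducer = "windows:2,3,4", classifier = "knn",
                       n_folds = 3L, seed = 23L)
  expect_identical(sum(ex$confusion), 60L)
  expect_gte(ex$accuracy, 95)
})

test_that("the PC1 reducer runs leak-free by default and on all data on request", {
  beats <- generate_dataset(15L, seed = 29L)
  strict <- run_experiment(beats, reducer = "pca1", classifier = "knn",
                           n_folds = 3L, seed = 29L)
  loose <- run_experiment(beats, reducer = "pca1", classifier = "knn",
                          n_folds = 3L, seed = 29L, reduce_on_all = TRUE)
  expect_identical(sum(strict$confusion), 60L)
  expect_identical(sum(loose$confusion), 60L)
  expect_gte(strict$accuracy, 90)
})

test_that("unknown reducer or classifier specs are rejected", {
  beats <- generate_dataset(3L, seed = 1L)
  expect_error(run_experiment(beats, reducer = "bogus"), "unknown reducer")
  expect_error(run_experiment(beats, classifier = "svm", n_folds = 2L),
               "unknown classifier")
})
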