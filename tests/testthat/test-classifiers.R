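test_that("KNN votes with the nearest-neighbour tie rule", {
  # k = 1 basics
  m1 <- knn_fit(matrix(c(0, 1), ncol = 1), c("A", "B"), k = 1L)
  expect_identical(as.character(knn_predict(m1, matrix(0.1))$labels), "A")
  expect_identical(as.character(knn_predict(m1, matrix(1))$labels), "B")
  # k = 4, 2-2 tie: neighbours at distances 1 (B), 2 (A), 3 (B), 4 (A);
  # nearest among the tied classes is B
  feats <- matrix(c(1, -2, 3, -4, 10), ncol = 1)
  labs <- c("B", "A", "B", "A", "A")
  m4 <- knn_fit(feats, labs, k = 4L)
  pred <- knn_predict(m4, matrix(0))
  expect_identical(as.character(pred$labels), "B")
  expect_equal(pred$confidence, -mean(c(1, 2, 3, 4)))
  expect_error(knn_fit(feats, labs, k = 6L), "between 1")
  expect_error(knn_fit(feats[0, , drop = FALSE], character(0)), "empty")
  expect_error(knn_predict(m4, matrix(0, ncol = 2)), "dimensionality")
})

test_that("KNN agrees with class::knn when there are no ties", {
  skip_if_not_installed("class")
  set.seed(44)
  blobs <- make_blobs(n_per_class = 25L, d = 4L, sep = 3, sd = 1.2)
  q <- make_blobs(n_per_class = 10L, d = 4L, sep = 3, sd = 1.2, seed = 2)
  model <- knn_fit(blobs$features, blobs$labels, k = 1L)
  mine <- knn_predict(model, q$features)$labels
  ref <- class::knn(blobs$features, q$features, blobs$labels, k = 1L)
  expect_identical(as.character(mine), as.character(ref))
})

test_that("PNN posteriors are Parzen class densities normalized to 1", {
  feats <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  m <- pnn_fit(feats, c("N", "S", "V", "F"), spread = 0.5)
  pred <- pnn_predict(m, rbind(c(0.1, 0), c(2, 2.2)))
  expect_equal(unname(rowSums(pred$posterior)), c(1, 1))
  expect_identical(as.character(pred$labels), c("N", "F"))
  # equidistant query from two single-sample classes: posterior split 50/50
  tie <- pnn_predict(pnn_fit(rbind(0, 2), c("A", "B"), spread = 0.3), matrix(1))
  expect_equal(unname(tie$posterior[1L, ]), c(0.5, 0.5))
  expect_error(pnn_fit(feats, c("N", "S", "V", "F"), spread = 0), "positive")
})

test_that("PNN converges to 1-NN as the spread shrinks", {
  set.seed(55)
  x <- matrix(runif(100), ncol = 2)
  y <- factor(rep(c("N", "V"), 25L))
  q <- matrix(runif(60), ncol = 2)
  nn1 <- knn_predict(knn_fit(x, y, k = 1L), q)$labels
  small <- pnn_predict(pnn_fit(x, y, spread = 0.01), q)$labels
  expect_identical(as.character(small), as.character(nn1))
  # full kernel underflow falls back to the nearest pattern unit, warning
  expect_warning(deep <- pnn_predict(pnn_fit(x, y, spread = 1e-9), q),
                 "zero density")
  expect_identical(as.character(deep$labels), as.character(nn1))
})

test_that("the network has the documented parameter count and softmax output", {
  expect_identical(mlp_n_params(c(75, 70, 60, 45, 30, 20, 10, 4)), 14579L)
  set.seed(66)
  blobs <- make_blobs(n_per_class = 10L, d = 6L)
  model <- mlp_train(blobs$features, blobs$labels, hidden = c(8, 6),
                     epochs = 5L, seed = 1L)
  p <- mlp_predict(model, blobs$features)$posterior
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-6)
  expect_true(all(p >= 0))
  expect_error(mlp_predict(model, matrix(0, ncol = 2)), "dimensionality")
})

test_that("softmax has the closed-form values and shift invariance", {
  sm <- scatbeat:::.softmax_rows
  expect_equal(unname(sm(matrix(c(0, 0, 0, 0), 1))[1, ]), rep(0.25, 4))
  expect_equal(unname(sm(matrix(c(1, 0, 0, 0), 1))[1, 1]), exp(1) / (exp(1) + 3))
  z <- matrix(rnorm(8), 2)
  expect_equal(sm(z), sm(z + 5))
})

test_that("the network separates a linearly separable toy set within 50 epochs", {
  set.seed(77)
  toy <- make_blobs(n_per_class = 5L, d = 4L, sep = 4, sd = 0.5)
  model <- mlp_train(toy$features, toy$labels, hidden = c(10, 6),
                     epochs = 50L, batch_size = 4L, learning_rate = 0.01,
                     seed = 2L)
  pred <- mlp_predict(model, toy$features)$labels
  expect_identical(as.character(pred), as.character(toy$labels))
  # deterministic given the seed
  model2 <- mlp_train(toy$features, toy$labels, hidden = c(10, 6),
                      epochs = 50L, batch_size = 4L, learning_rate = 0.01,
                      seed = 2L)
  expect_identical(model$weights, model2$weights)
})

test_that("all three classifiers clear 95% on well-separated blobs", {
  blobs <- make_blobs(n_per_class = 40L, d = 8L, sep = 8, sd = 1, seed = 10L)
  test <- make_blobs(n_per_class = 15L, d = 8L, sep = 8, sd = 1, seed = 11L)
  acc <- function(pred) mean(as.character(pred) == as.character(test$labels))
  expect_gte(acc(knn_predict(knn_fit(blobs$features, blobs$labels, k = 4L),
                             test$features)$labels), 0.95)
  expect_gte(acc(pnn_predict(pnn_fit(blobs$features, blobs$labels, spread = 1),
                             test$features)$labels), 0.95)
  nn <- mlp_train(blobs$features, blobs$labels, hidden = c(16, 8),
                  epochs = 40L, batch_size = 16L, learning_rate = 0.01, seed = 3L)
  expect_gte(acc(mlp_predict(nn, test$features)$labels), 0.95)
})
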