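#' Stratified cross-validation folds
#'
#' Randomly partitions the beats into `n_folds` folds, stratified by class
#' so every fold holds (up to rounding) the same number of beats of each
#' class. Reproducible given the seed.
#'
#' @param labels Class labels, one per beat.
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold assignments in `1..n_folds`, one per
#'   beat.
#' @export
make_folds <- function(labels, n_folds = 10L, seed = 1L) {
  labels <- as.factor(labels)
  if (n_folds < 2L) {
    stop("`n_folds` must be at least 2")
  }
  counts <- table(labels)
  if (any(counts < n_folds)) {
    stop("every class needs at least `n_folds` members; too small: ",
         paste(names(counts)[counts < n_folds], collapse = ", "))
  }
  restore <- .with_seed_state(seed)
  on.exit(restore(), add = TRUE)
  folds <- integer(length(labels))
  offset <- 0L
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    # balanced fold-id multiset; remainders rotate across classes so
    # overall fold sizes differ by at most one
    ids <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
    folds[idx] <- sample(ids)
    offset <- (offset + length(idx)) %% n_folds
  }
  folds
}

#' Aggregate per-window predictions into one beat label
#'
#' The most frequent window label wins; a tie between labels is broken by
#' the highest summed confidence (softmax or PNN posterior, or negative
#' mean KNN neighbour distance).
#'
#' @param labels Factor/character of window-level predicted labels.
#' @param confidence Numeric confidences, one per window prediction.
#' @param beat_index Source beat of each window prediction; votes are
#'   grouped by this index. If omitted, all predictions belong to one
#'   beat.
#' @return Factor of beat-level labels, one per distinct `beat_index`, in
#'   order of first appearance sorted by index.
#' @export
majority_vote <- function(labels, confidence = NULL, beat_index = NULL) {
  labels <- as.factor(labels)
  if (is.null(beat_index)) {
    beat_index <- rep(1L, length(labels))
  }
  if (is.null(confidence)) {
    confidence <- rep(0, length(labels))
  }
  stopifnot(length(labels) == length(beat_index),
            length(labels) == length(confidence))
  out <- vapply(split(seq_along(labels), beat_index), function(ix) {
    votes <- table(labels[ix])
    best <- names(votes)[votes == max(votes)]
    if (length(best) > 1L) {
      conf_sum <- vapply(best, function(cl) {
        sum(confidence[ix][labels[ix] == cl])
      }, numeric(1))
      best <- best[which.max(conf_sum)]
    }
    best
  }, character(1))
  ord <- order(as.numeric(names(out)))
  factor(out[ord], levels = levels(labels))
}

#' Confusion matrix over the four AAMI classes
#'
#' @param true_labels,predicted_labels Vectors of classes in
#'   `N, S, V, F`; equal length.
#' @return A `confusion_matrix` object: an integer matrix with true
#'   classes as rows and predicted classes as columns, in the fixed order
#'   N, S, V, F.
#' @export
confusion_matrix <- function(true_labels, predicted_labels) {
  cls <- aami_classes()
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must have equal length")
  }
  bad <- setdiff(unique(c(true_labels, predicted_labels)), cls)
  if (length(bad)) {
    stop("labels outside {N, S, V, F}: ", paste(bad, collapse = ", "))
  }
  m <- table(factor(true_labels, levels = cls),
             factor(predicted_labels, levels = cls))
  structure(matrix(as.integer(m), nrow = 4L, dimnames = list(true = cls, predicted = cls)),
            class = c("confusion_matrix", "matrix"))
}

#' Build a confusion matrix from counts
#'
#' Convenience constructor for a 4x4 count matrix already in N, S, V, F
#' order (rows = true classes), e.g. when re-evaluating published tables.
#'
#' @param counts 4x4 numeric matrix of counts.
#' @return A `confusion_matrix` object.
#' @export
as_confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4L, ncol(counts) == 4L, all(counts >= 0))
  cls <- aami_classes()
  structure(matrix(as.integer(round(counts)), nrow = 4L,
                   dimnames = list(true = cls, predicted = cls)),
            class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted)\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class PPV, sensitivity and specificity
#'
#' For class `c` with confusion matrix `cm`: sensitivity is
#' `cm[c,c] / rowsum(c)`, positive predictive value is
#' `cm[c,c] / colsum(c)`, and specificity is `TN / (TN + FP)` with
#' `FP = colsum(c) - cm[c,c]` and `TN = total - rowsum(c) - FP`. Values
#' are percentages; a zero denominator yields `NA` (undefined), never 0.
#'
#' @param cm A [confusion_matrix()].
#' @return Data frame with one row per class and columns `class`, `ppv`,
#'   `sen`, `spec` (percent).
#' @export
per_class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0) {
    stop("empty confusion matrix")
  }
  cls <- rownames(cm)
  res <- lapply(seq_along(cls), function(i) {
    tp <- cm[i, i]
    rs <- sum(cm[i, ])
    cs <- sum(cm[, i])
    fp <- cs - tp
    tn <- total - rs - fp
    data.frame(
      class = cls[i],
      ppv = if (cs > 0) 100 * tp / cs else NA_real_,
      sen = if (rs > 0) 100 * tp / rs else NA_real_,
      spec = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
    )
  })
  do.call(rbind, res)
}

#' Normal-versus-abnormal (binary collapse) metrics
#'
#' Collapses the 4x4 matrix to a binary problem with N as the negative
#' class: TP = abnormal beats (S, V, F) predicted as any abnormal class,
#' FN = abnormal beats predicted N, FP = N beats predicted abnormal,
#' TN = N beats predicted N. Reports the counts and ACC, PPV, SEN, SPEC in
#' percent (`NA` on a zero denominator).
#'
#' @param cm A [confusion_matrix()].
#' @return One-row data frame with `tp`, `tn`, `fp`, `fn`, `acc`, `ppv`,
#'   `sen`, `spec`.
#' @export
binary_collapse_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  abn <- 2:4
  tp <- sum(cm[abn, abn])
  fn <- sum(cm[abn, 1L])
  fp <- sum(cm[1L, abn])
  tn <- cm[1L, 1L]
  total <- tp + tn + fp + fn
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  data.frame(tp = tp, tn = tn, fp = fp, fn = fn,
             acc = pct(tp + tn, total),
             ppv = pct(tp, tp + fp),
             sen = pct(tp, tp + fn),
             spec = pct(tn, tn + fp))
}

#' Overall multiclass accuracy
#'
#' @param cm A [confusion_matrix()].
#' @return Percent of beats on the diagonal.
#' @export
overall_accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  100 * sum(diag(cm)) / sum(cm)
}

# Fit/predict dispatch shared by run_experiment and the CLI.
.fit_classifier <- function(classifier, features, labels, params, seed) {
  switch(classifier,
    knn = knn_fit(features, labels, k = params$k %||% 4L),
    pnn = pnn_fit(features, labels, spread = params$spread %||% 0.01),
    nn = mlp_train(features, labels,
                   hidden = params$hidden %||% c(70, 60, 45, 30, 20, 10),
                   epochs = params$epochs %||% 50L,
                   batch_size = params$batch_size %||% 256L,
                   learning_rate = params$learning_rate %||% 1e-3,
                   seed = seed),
    stop("unknown classifier: ", classifier)
  )
}

.predict_classifier <- function(model, features) {
  if (inherits(model, "knn_model")) {
    knn_predict(model, features)
  } else if (inherits(model, "pnn_model")) {
    pnn_predict(model, features)
  } else {
    mlp_predict(model, features)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parse a reducer spec string into a closure over (batch, fit_on).
.reducer_fun <- function(reducer) {
  if (identical(reducer, "windows-all")) {
    return(function(batch, fit_on) expand_window_rows(batch))
  }
  if (identical(reducer, "pca1")) {
    return(function(batch, fit_on) per_node_pc1(batch, fit_on = fit_on))
  }
  if (grepl("^window:[0-9]+$", reducer)) {
    w <- as.integer(sub("^window:", "", reducer))
    return(function(batch, fit_on) select_window(batch, w))
  }
  if (grepl("^windows:[0-9]+(,[0-9]+)*$", reducer)) {
    ws <- as.integer(strsplit(sub("^windows:", "", reducer), ",")[[1L]])
    return(function(batch, fit_on) select_window_subset(batch, ws))
  }
  stop("unknown reducer spec: ", reducer,
       " (expected windows-all, window:<i>, windows:<i,j,...> or pca1)")
}

#' Cross-validated beat-classification experiment
#'
#' Runs the full pipeline on a set of labelled beats: scattering transform,
#' the chosen window reduction, stratified k-fold cross-validation with the
#' chosen classifier, per-beat majority voting when a beat contributes
#' several window rows, and confusion counts accumulated over the folds so
#' every beat is tested exactly once.
#'
#' The `pca1` reducer is fitted on the training folds only by default; set
#' `reduce_on_all = TRUE` to fit it on all beats.
#'
#' @param beats A [beat_set()].
#' @param config A [scattering_config()] (defaults to the standard
#'   architecture).
#' @param reducer One of `"windows-all"`, `"window:<i>"` (0-based),
#'   `"windows:<i,j,...>"`, `"pca1"`.
#' @param classifier One of `"knn"`, `"pnn"`, `"nn"`.
#' @param n_folds Number of cross-validation folds.
#' @param seed Integer seed controlling fold assignment and (for the
#'   neural network) training.
#' @param params Named list of classifier hyperparameters (`k`, `spread`,
#'   `epochs`, `batch_size`, `learning_rate`, `hidden`).
#' @param reduce_on_all Fit the PC1 reducer on all beats instead of the
#'   training folds only.
#' @return A list of class `scatbeat_experiment`: `confusion`
#'   (accumulated [confusion_matrix()]), `per_class`
#'   ([per_class_metrics()]), `binary` ([binary_collapse_metrics()]),
#'   `accuracy`, `folds`, and the configuration used.
#' @export
run_experiment <- function(beats, config = scattering_config(),
                           reducer = "window:3", classifier = "knn",
                           n_folds = 10L, seed = 1L, params = list(),
                           reduce_on_all = FALSE) {
  stopifnot(inherits(beats, "beat_set"))
  reduce <- .reducer_fun(reducer)
  if (!classifier %in% c("knn", "pnn", "nn")) {
    stop("unknown classifier: ", classifier)
  }
  bank <- build_filter_banks(config)
  batch <- transform_batch(beats, bank)
  folds <- make_folds(batch$labels, n_folds = n_folds, seed = seed)

  n <- length(batch$labels)
  predicted <- factor(rep(NA_character_, n), levels = aami_classes())
  for (f in seq_len(n_folds)) {
    test_beats <- which(folds == f)
    train_beats <- which(folds != f)
    fm <- reduce(batch, if (reduce_on_all) NULL else train_beats)
    in_train <- fm$beat_index %in% train_beats
    in_test <- fm$beat_index %in% test_beats
    model <- .fit_classifier(classifier,
                             fm$features[in_train, , drop = FALSE],
                             fm$labels[in_train],
                             params, seed = seed + f)
    pred <- .predict_classifier(model, fm$features[in_test, , drop = FALSE])
    beat_lab <- majority_vote(pred$labels, pred$confidence,
                              fm$beat_index[in_test])
    predicted[sort(unique(fm$beat_index[in_test]))] <- beat_lab
  }

  cm <- confusion_matrix(batch$labels, predicted)
  structure(
    list(confusion = cm,
         per_class = per_class_metrics(cm),
         binary = binary_collapse_metrics(cm),
         accuracy = overall_accuracy(cm),
         folds = folds,
         reducer = reducer,
         classifier = classifier,
         n_folds = as.integer(n_folds),
         seed = as.integer(seed),
         config = config),
    class = "scatbeat_experiment"
  )
}

#' @export
print.scatbeat_experiment <- function(x, ...) {
  cat(sprintf("Experiment: %s + %s, %d-fold CV, seed %d\n",
              x$reducer, x$classifier, x$n_folds, x$seed))
  print(x$confusion)
  pc <- x$per_class
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  %s: PPV %5.1f  SEN %5.1f  SPEC %5.1f\n",
                pc$class[i], pc$ppv[i], pc$sen[i], pc$spec[i]))
  }
  b <- x$binary
  cat(sprintf("  binary (N vs abnormal): TP %d TN %d FP %d FN %d\n",
              b$tp, b$tn, b$fp, b$fn))
  cat(sprintf("  ACC %.1f  PPV %.1f  SEN %.1f  SPEC %.1f\n",
              b$acc, b$ppv, b$sen, b$spec))
  invisible(x)
}
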