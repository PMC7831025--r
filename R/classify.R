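#' Euclidean distance between two vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return `sqrt(sum((a - b)^2))`.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b))
    stop_cp("dimension mismatch: %d vs %d", length(a), length(b))
  sqrt(sum((a - b)^2))
}

# Squared Euclidean cross-distances: rows of A vs rows of B.
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  pmax(d2, 0)
}

#' K-nearest-neighbors configuration
#'
#' @param k Neighbor count (default 5); a warning is emitted for even `k`
#'   (ties become more frequent).
#' @param metric Distance metric; only `"euclidean"` is implemented.
#' @return A `KNNConfig`.
#' @export
knn_config <- function(k = 5, metric = "euclidean") {
  stopifnot(k >= 1, metric == "euclidean")
  if (k %% 2 == 0) warning("even k invites ties; odd k recommended", call. = FALSE)
  structure(list(k = as.integer(k), metric = metric), class = "KNNConfig")
}

#' K-nearest-neighbors prediction
#'
#' Each test sample is assigned the majority label among its `k` nearest
#' training samples under the Euclidean metric. Tie handling is
#' deterministic: equal distances at the k-th rank are resolved by training
#' order (stable sort); tied majority votes are resolved in favor of the
#' class with the smaller summed neighbor distance, then lexicographic class
#' order.
#'
#' @param train Training sample matrix (rows = samples).
#' @param labels Character vector of training labels (one per row).
#' @param test Test sample matrix (same number of columns).
#' @param config A [knn_config()].
#' @return Character vector of predicted labels, one per test row.
#' @export
knn_predict <- function(train, labels, test, config = knn_config()) {
  stopifnot(is.matrix(train), is.matrix(test))
  if (nrow(train) == 0) stop_cp("empty training set")
  if (ncol(train) != ncol(test))
    stop_cp("dimension mismatch: train %d vs test %d", ncol(train), ncol(test))
  if (length(labels) != nrow(train))
    stop_cp("labels length must match training rows")
  k <- min(config$k, nrow(train))
  d2 <- cross_dist2(test, train)
  preds <- character(nrow(test))
  for (i in seq_len(nrow(test))) {
    ord <- order(d2[i, ])[seq_len(k)]  # stable: ties by training index
    nb_lab <- labels[ord]
    nb_d <- sqrt(d2[i, ord])
    votes <- table(nb_lab)
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      sums <- vapply(top, function(cl) sum(nb_d[nb_lab == cl]), numeric(1))
      top <- top[sums == min(sums)]
      top <- sort(top)[1]
    }
    preds[i] <- top
  }
  preds
}

#' Confusion matrix of true versus predicted labels
#'
#' @param true,predicted Character vectors of equal length.
#' @param classes Ordered class names (default: sorted union).
#' @return Square integer matrix of counts with classes as dimnames
#'   (rows = true, columns = predicted), class `ConfusionMatrix`.
#' @export
confusion_matrix <- function(true, predicted, classes = NULL) {
  stopifnot(length(true) == length(predicted))
  classes <- classes %||% sort(union(true, predicted))
  cm <- table(factor(true, levels = classes),
              factor(predicted, levels = classes))
  out <- matrix(as.integer(cm), nrow = length(classes),
                dimnames = list(true = classes, predicted = classes))
  structure(out, class = c("ConfusionMatrix", "matrix"))
}

#' Classification accuracy from a confusion matrix
#'
#' The percentage of samples on the diagonal:
#' `100 * sum(diag(cm)) / sum(cm)` (for the binary case this is
#' `(TP + TN) / (TP + TN + FP + FN) * 100`).
#'
#' @param cm Square numeric matrix of counts.
#' @return Accuracy in percent.
#' @export
accuracy <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  tot <- sum(cm)
  if (tot <= 0) stop_cp("empty confusion matrix")
  100 * sum(diag(cm)) / tot
}

#' Cross-validated KNN classification at one potential
#'
#' Runs the full leave-one-recording-per-class cross-validation: for every
#' fold, the fold is preprocessed (truncate, window, PAA, scale), a KNN
#' classifier is fitted on the 200-dimensional training windows (never on a
#' latent embedding) and the test windows are predicted. Per-fold confusion
#' matrices are summed into the overall matrix from which the accuracy is
#' computed; the unweighted per-fold mean accuracy is also reported.
#'
#' @param recordings Named list of `Recording`s at a single potential,
#'   >= 2 per class.
#' @param config A [preprocess_config()].
#' @param knn A [knn_config()].
#' @return A `CVResult`: list with `per_fold` (fold_id + `ConfusionMatrix`),
#'   `overall` (summed matrix), `accuracy` (percent), `fold_mean_accuracy`,
#'   `classes`.
#' @export
run_cross_validation <- function(recordings, config = preprocess_config(),
                                 knn = knn_config()) {
  pots <- unique(vapply(recordings, function(r) r$potential, numeric(1)))
  if (length(pots) != 1)
    stop_cp("recordings span %d potentials; classify one potential at a time",
            length(pots))
  classes <- sort(unique(vapply(recordings, function(r) r$cell_label, character(1))))
  folds <- make_cv_folds(recordings)
  per_fold <- vector("list", length(folds))
  overall <- matrix(0L, length(classes), length(classes),
                    dimnames = list(true = classes, predicted = classes))
  fold_acc <- numeric(length(folds))
  for (i in seq_along(folds)) {
    pp <- preprocess_fold(folds[[i]], recordings, config)
    preds <- knn_predict(pp$train, pp$train_meta$cell_label, pp$test, knn)
    cm <- confusion_matrix(pp$test_meta$cell_label, preds, classes)
    per_fold[[i]] <- list(fold_id = folds[[i]]$fold_id, confusion = cm)
    overall <- overall + cm
    fold_acc[i] <- accuracy(cm)
  }
  structure(list(per_fold = per_fold,
                 overall = structure(overall,
                                     class = c("ConfusionMatrix", "matrix")),
                 accuracy = accuracy(overall),
                 fold_mean_accuracy = mean(fold_acc),
                 classes = classes,
                 n_folds = length(folds)),
            class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("<CVResult> %d folds, overall accuracy %.2f%% (fold mean %.2f%%)\n",
              x$n_folds, x$accuracy, x$fold_mean_accuracy))
  print(unclass(x$overall))
  invisible(x)
}
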