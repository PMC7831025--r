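test_that("euclidean distance has the 3-4-5 value and metric properties", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(1:7, 1:7), 0)
  expect_error(euclidean_distance(1:3, 1:4), "dimension")
  set.seed(51)
  for (i in 1:1000) {
    a <- rnorm(4); b <- rnorm(4); c <- rnorm(4)
    expect_lte(euclidean_distance(a, c),
               euclidean_distance(a, b) + euclidean_distance(b, c) + 1e-12)
    expect_equal(euclidean_distance(a, b), euclidean_distance(b, a))
  }
})

test_that("knn prediction matches a brute-force oracle and handles ties", {
  # exact-match with k = 1
  train <- matrix(c(0, 0, 10, 10), 2, byrow = TRUE)
  expect_equal(knn_predict(train, c("A", "B"), train, knn_config(k = 1)),
               c("A", "B"))
  # majority 3 A vs 2 B
  tr <- rbind(matrix(0.1 * 1:6, 3), matrix(5 + 0.1 * 1:6, 3))
  expect_equal(knn_predict(tr, c("A", "A", "A", "B", "B", "B"),
                           matrix(c(0.2, 0.5), 1), knn_config(k = 5)), "A")

  # oracle equivalence on random instances
  set.seed(52)
  brute_knn <- function(train, labels, test, k) {
    apply(test, 1, function(x) {
      d <- sqrt(colSums((t(train) - x)^2))
      nb <- order(d)[seq_len(k)]
      v <- table(labels[nb])
      top <- names(v)[v == max(v)]
      if (length(top) > 1) {
        sums <- vapply(top, function(cl) sum(d[nb][labels[nb] == cl]), numeric(1))
        top <- sort(top[sums == min(sums)])[1]
      }
      top
    })
  }
  for (i in 1:20) {
    n <- sample(20:60, 1); d <- sample(2:5, 1)
    train <- matrix(rnorm(n * d), n)
    labels <- sample(c("A", "B", "C"), n, replace = TRUE)
    while (length(unique(labels)) < 2) labels <- sample(c("A", "B", "C"), n, TRUE)
    test <- matrix(rnorm(10 * d), 10)
    k <- sample(c(1, 3, 5), 1)
    expect_equal(knn_predict(train, labels, test, knn_config(k = k)),
                 unname(brute_knn(train, labels, test, k)))
  }

  # training-order permutation invariance
  set.seed(53)
  train <- matrix(rnorm(80), 20)
  labels <- rep(c("A", "B"), each = 10)
  test <- matrix(rnorm(20), 5)
  perm <- sample(20)
  expect_equal(knn_predict(train, labels, test),
               knn_predict(train[perm, ], labels[perm], test))
  expect_error(knn_predict(matrix(numeric(0), 0, 4), character(0), test), "empty")
})

test_that("confusion matrices and accuracy follow the diagonal-ratio definition", {
  # binary: TP=2, TN=3, FP=1, FN=0 -> 83.33%
  cm <- matrix(c(2, 0, 1, 3), 2, dimnames = list(c("pos", "neg"), c("pos", "neg")))
  expect_equal(accuracy(cm), 100 * 5 / 6, tolerance = 1e-10)
  expect_equal(round(accuracy(cm), 2), 83.33)
  # perfect diagonal
  expect_equal(accuracy(diag(c(5, 9, 3))), 100)
  # 30 on-diagonal + 3 errors -> 90.91%
  cm3 <- diag(c(10, 10, 10)); cm3[1, 2] <- 2; cm3[3, 1] <- 1
  expect_equal(accuracy(cm3), 100 * 30 / 33)
  expect_error(accuracy(matrix(0, 2, 2)), "empty")

  got <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
  expect_equal(as.vector(got), c(1L, 0L, 1L, 1L))
  expect_equal(rownames(got), c("a", "b"))
})

test_that("cross-validated KNN separates the well-separated fixture", {
  ds <- fix_small_dataset()
  cv <- run_cross_validation(ds$recordings)
  expect_s3_class(cv, "CVResult")
  expect_equal(cv$n_folds, 27)
  # per-fold matrices sum exactly to the overall matrix
  summed <- Reduce(`+`, lapply(cv$per_fold, `[[`, "confusion"))
  expect_equal(unclass(cv$overall), unclass(summed), ignore_attr = TRUE)
  expect_equal(cv$accuracy, 100 * sum(diag(cv$overall)) / sum(cv$overall))
  expect_gt(cv$accuracy, 95)
  # classification consumes 200-dimensional samples (never the embedding)
  folds <- make_cv_folds(ds$recordings)
  pp <- preprocess_fold(folds[[1]], ds$recordings)
  expect_equal(ncol(pp$train), 200)
})

test_that("label permutation collapses accuracy to the chance band", {
  ds <- fix_small_dataset()
  ctrl <- permutation_control(ds$recordings, seed = 54, n_shuffles = 3)
  expect_gt(ctrl$accuracy, 15)
  expect_lt(ctrl$accuracy, 50)
})
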