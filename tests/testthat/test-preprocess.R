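test_that("truncation keeps equal-length prefixes", {
  recs <- list(a = new_recording("a", "x", 0, 1:5, 4000),
               b = new_recording("b", "x", 0, 11:13, 4000),
               c = new_recording("c", "x", 0, 21:24, 4000))
  tr <- truncate_to_shortest(recs)
  expect_equal(vapply(tr, function(r) length(r$trace), integer(1)),
               c(a = 3L, b = 3L, c = 3L))
  expect_equal(tr$a$trace, c(1, 2, 3))  # prefix kept
  expect_identical(names(tr), names(recs))
  same <- truncate_to_shortest(recs[c("b")])
  expect_equal(same$b$trace, recs$b$trace)
})

test_that("window extraction follows the floor((L-l)/r) count and matches enumeration", {
  w <- split_windows(seq_len(2000), 1000, 200)
  expect_equal(nrow(w), 5)
  expect_equal(attr(w, "offsets"), c(0, 200, 400, 600, 800))
  expect_equal(w[2, 1], 201)  # second window starts at point 201 (1-based)

  expect_equal(nrow(split_windows(seq_len(1000), 1000, 200)), 0)  # L = l
  w2 <- split_windows(seq_len(1400), 1000, 200)
  expect_equal(attr(w2, "offsets"), c(0, 200))
  expect_warning(split_windows(1:10, 100, 10), "no windows")

  # brute-force enumeration oracle over randomized geometries
  set.seed(71)
  for (i in 1:100) {
    L <- sample(50:400, 1)
    l <- sample(10:min(100, L), 1)
    r <- sample(1:l, 1)
    tr <- rnorm(L)
    got <- split_windows(tr, l, r)
    n_expected <- (L - l) %/% r
    expect_equal(nrow(got), n_expected)
    for (k in seq_len(n_expected)) {
      expect_identical(got[k, ], tr[((k - 1) * r + 1):((k - 1) * r + l)])
    }
  }
})

test_that("PAA equals brute-force frame means and preserves the mean", {
  expect_equal(paa(c(1, 2, 3, 4, 5, 6), 3), c(1.5, 3.5, 5.5))
  expect_equal(paa(rep(7, 20), 4), rep(7, 4))
  expect_equal(paa(1:12, 12), as.numeric(1:12))  # idempotent at w = l
  expect_error(paa(1:10, 3), "divisible")

  set.seed(72)
  for (i in 1:100) {
    w <- sample(1:10, 1)
    frame <- sample(1:8, 1)
    x <- rnorm(w * frame)
    oracle <- vapply(seq_len(w),
                     function(j) mean(x[((j - 1) * frame + 1):(j * frame)]),
                     numeric(1))
    expect_equal(paa(x, w), oracle)
  }
  # 1000 -> 200 points, mean preserved; matrix form agrees with vector form
  x <- rnorm(1000)
  got <- paa(x, 200)
  expect_length(got, 200)
  expect_equal(mean(got), mean(x))
  m <- rbind(x, x)
  expect_equal(paa(m, 200)[1, ], got)
})

test_that("min-max scaling maps train to [0,1] and clips test", {
  train <- matrix(c(2, 3, 5, 6), 2)
  sc <- minmax_scale(train, matrix(c(4, 7, 1), 1))
  expect_equal(min(sc$train), 0)
  expect_equal(max(sc$train), 1)
  expect_equal(sc$test[1, 1], 0.5)       # value 4 in [2, 6]
  expect_equal(sc$test[1, 2:3], c(1, 0)) # clipped
  expect_equal(sc$n_clipped, 2)
  expect_error(minmax_scale(matrix(1, 2, 2)), "constant")
})

test_that("cross-validation folds enumerate the per-class Cartesian product", {
  mk <- function(id, lab) new_recording(id, lab, 40, rnorm(10), 4000)
  set.seed(73)
  recs <- list(mk("a1", "A"), mk("a2", "A"), mk("a3", "A"),
               mk("b1", "B"), mk("b2", "B"), mk("b3", "B"),
               mk("c1", "C"), mk("c2", "C"), mk("c3", "C"))
  names(recs) <- vapply(recs, `[[`, character(1), "recording_id")
  folds <- make_cv_folds(recs)
  expect_equal(length(folds), 27)
  combos <- t(vapply(folds, `[[`, character(3), "test_recordings"))
  expect_equal(nrow(unique(combos)), 27)
  # every fold partitions the recordings
  for (f in folds) {
    expect_length(intersect(f$test_recordings, f$train_recordings), 0)
    expect_setequal(c(f$test_recordings, f$train_recordings), names(recs))
  }
  # unbalanced classes: 2 * 3 * 4 folds
  recs2 <- c(recs[c("a1", "a2")], recs[4:9],
             list(c4 = mk("c4", "C")))
  folds2 <- make_cv_folds(recs2)
  expect_equal(length(folds2), 24)
  # a class with one recording fails by name
  expect_error(make_cv_folds(recs[c(1, 4, 5, 7, 8)]), "A")
})

test_that("preprocess_fold yields labelled, scaled, balanced samples", {
  ds <- fix_small_dataset()
  folds <- make_cv_folds(ds$recordings)
  pp <- preprocess_fold(folds[[1]], ds$recordings)
  # 12000 points -> floor((12000-1000)/200) = 55 windows per recording
  expect_equal(nrow(pp$test), 3 * 55)
  expect_equal(nrow(pp$train), 6 * 55)
  expect_equal(ncol(pp$train), 200)
  expect_equal(as.vector(table(pp$test_meta$cell_label)), rep(55, 3))
  expect_true(all(pp$train >= 0 & pp$train <= 1))
  expect_true(all(pp$test >= 0 & pp$test <= 1))
  expect_equal(nrow(pp$train_meta), nrow(pp$train))
  # determinism
  pp2 <- preprocess_fold(folds[[1]], ds$recordings)
  expect_identical(pp, pp2)
  # joint scope scales train and test together
  ppj <- preprocess_fold(folds[[1]], ds$recordings,
                         preprocess_config(normalization_scope = "joint"))
  expect_equal(ppj$scaling$n_clipped, 0)
  expect_equal(max(rbind(ppj$train, ppj$test)), 1)
})
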