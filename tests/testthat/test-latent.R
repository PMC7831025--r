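test_that("k-means recovers separated pairs and obeys Lloyd properties", {
  X <- rbind(c(0, 0), c(0, 0.1), c(1, 1), c(1, 0.9))
  res <- kmeans_lloyd(X, 2, seed = 61)
  cent <- res$centroids[order(res$centroids[, 1]), ]
  expect_equal(unname(cent), rbind(c(0, 0.05), c(1, 0.95)))
  expect_equal(length(unique(res$assignments)), 2)
  # K = 1: centroid is the mean
  set.seed(62)
  Y <- matrix(rnorm(40), 20)
  res1 <- kmeans_lloyd(Y, 1, seed = 1, n_init = 2)
  expect_equal(unname(res1$centroids[1, ]), unname(colMeans(Y)))
  # inertia trajectory is non-increasing
  res2 <- kmeans_lloyd(Y, 3, seed = 2)
  expect_true(all(diff(res2$inertia_trace) <= 1e-9))
  # returned inertia is the best across restarts
  expect_equal(res2$inertia, min(res2$restart_inertias))
  expect_error(kmeans_lloyd(rbind(c(1, 1), c(1, 1)), 2), "distinct")
})

test_that("k-means assignments agree with stats::kmeans and a nearest-centroid oracle", {
  set.seed(63)
  X <- rbind(cbind(rnorm(30, 0), rnorm(30, 0)),
             cbind(rnorm(30, 4), rnorm(30, 4)),
             cbind(rnorm(30, 8), rnorm(30, 0)))
  res <- kmeans_lloyd(X, 3, seed = 64, n_init = 10)
  # at convergence every point sits with its nearest centroid
  d2 <- outer(rowSums(X^2), rowSums(res$centroids^2), "+") -
    2 * X %*% t(res$centroids)
  expect_equal(res$assignments, unname(max.col(-d2, ties.method = "first")))
  # the reference implementation reaches the same partition and inertia
  ref <- stats::kmeans(X, 3, nstart = 10, algorithm = "Lloyd")
  expect_equal(res$inertia, ref$tot.withinss, tolerance = 1e-6)
  agree <- table(res$assignments, ref$cluster)
  expect_equal(sum(apply(agree, 1, max)), nrow(X))  # identical partition
})

test_that("cluster-to-class mapping resolves collisions by max agreement", {
  res <- list(assignments = c(1, 1, 2, 2, 3, 3), K = 3)
  map <- map_clusters_to_classes(res, c("a", "a", "b", "b", "c", "c"))
  expect_equal(as.character(map), c("a", "b", "c"))
  expect_equal(attr(map, "agreement"), 1)

  # collision: clusters 1 and 2 both majority-"a"; permutation search fixes it
  res2 <- list(assignments = c(1, 1, 1, 2, 2, 2, 3, 3, 3), K = 3)
  labs <- c("a", "a", "a", "a", "a", "b", "c", "c", "c")
  map2 <- map_clusters_to_classes(res2, labs)
  expect_setequal(unname(map2), c("a", "b", "c"))
  # brute-force over all 6 permutations
  perms <- channelprint:::permutations_of(c("a", "b", "c"))
  agr <- vapply(perms, function(p) {
    mean(p[res2$assignments] == labs)
  }, numeric(1))
  expect_equal(attr(map2, "agreement"), max(agr))

  expect_warning(map_clusters_to_classes(
    list(assignments = c(1, 2), K = 2), c("a", "a")), "one class")
})

test_that("centroid distances have exact values and symmetry", {
  res <- list(centroids = rbind(c(0, 0), c(3, 4), c(0, 1)), K = 3)
  map <- stats::setNames(c("endo", "fibro", "hippo"), 1:3)
  d <- centroid_distances(res, map)
  expect_equal(unname(d["endo-fibro"]), 5)
  expect_equal(unname(d["endo-hippo"]), 1)
  expect_equal(unname(d["fibro-hippo"]), sqrt(18))
  expect_error(centroid_distances(res, stats::setNames(rep("endo", 3), 1:3)),
               "bijective")
})

test_that("embedding and clustering separate the well-separated fixture", {
  ds <- fix_small_dataset()
  pp <- preprocess_pooled(ds$recordings)
  ec <- embed_and_cluster(pp$x, pp$meta$cell_label,
                          hp = train_hyperparams(epochs = 60, seed = 65),
                          seed = 66)
  expect_gte(ec$agreement, 0.9)
  expect_length(ec$distances, 3)
  expect_true(all(ec$distances > 0))
  expect_true(all(ec$embedding > 0 & ec$embedding < 1))
  # determinism
  ec2 <- embed_and_cluster(pp$x, pp$meta$cell_label,
                           hp = train_hyperparams(epochs = 60, seed = 65),
                           seed = 66)
  expect_identical(ec$distances, ec2$distances)
  expect_error(embed_and_cluster(pp$x, rep("one", nrow(pp$x))), "2 classes")
})
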