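#' K-means clustering (Lloyd's algorithm)
#'
#' Lloyd iterations from a random choice of K distinct data points as initial
#' centroids, Euclidean metric, repeated for `n_init` restarts; the restart
#' with the lowest within-cluster sum of squares (inertia) is returned along
#' with its inertia trajectory (non-increasing across iterations). Empty
#' clusters are re-seeded with the point farthest from its centroid.
#'
#' @param X Point matrix (rows = points); at least `K` distinct rows.
#' @param K Number of clusters.
#' @param seed Integer seed for the initializations.
#' @param n_init Number of random restarts.
#' @param max_iter Iteration cap per restart.
#' @return A `ClusterResult`: list with `centroids` (K x d), `assignments`,
#'   `inertia`, `inertia_trace`, `restart_inertias`.
#' @export
kmeans_lloyd <- function(X, K, seed = 1, n_init = 10, max_iter = 100) {
  stopifnot(is.matrix(X), K >= 1)
  if (nrow(unique(X)) < K)
    stop_cp("K = %d exceeds the number of distinct points (%d)",
            K, nrow(unique(X)))
  run_once <- function() {
    init <- sample.int(nrow(X), K)
    # ensure distinct initial centroids
    while (nrow(unique(X[init, , drop = FALSE])) < K) {
      init <- sample.int(nrow(X), K)
    }
    C <- X[init, , drop = FALSE]
    assign_old <- rep(0L, nrow(X))
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      d2 <- cross_dist2(X, C)
      assign_new <- max.col(-d2, ties.method = "first")
      for (kk in seq_len(K)) {
        members <- which(assign_new == kk)
        if (length(members) == 0) {
          # re-seed an empty cluster with the worst-fit point
          far <- which.max(d2[cbind(seq_len(nrow(X)), assign_new)])
          assign_new[far] <- kk
          members <- far
        }
        C[kk, ] <- colMeans(X[members, , drop = FALSE])
      }
      d2 <- cross_dist2(X, C)
      assign_new <- max.col(-d2, ties.method = "first")
      trace <- c(trace, sum(d2[cbind(seq_len(nrow(X)), assign_new)]))
      if (all(assign_new == assign_old)) break
      assign_old <- assign_new
    }
    list(centroids = C, assignments = assign_new,
         inertia = trace[length(trace)], inertia_trace = trace)
  }
  with_seed(seed, {
    runs <- lapply(seq_len(n_init), function(i) run_once())
    inertias <- vapply(runs, `[[`, numeric(1), "inertia")
    best <- runs[[which.min(inertias)]]
    structure(c(best, list(restart_inertias = inertias, K = K)),
              class = "ClusterResult")
  })
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("<ClusterResult> K = %d, inertia = %.4g (%d restarts)\n",
              x$K, x$inertia, length(x$restart_inertias)))
  invisible(x)
}

#' Map clusters to class names by majority vote
#'
#' Each cluster is mapped to the majority true class among its members; when
#' two clusters claim the same majority class (and K equals the number of
#' classes), the collision is resolved by the exhaustive permutation of
#' class assignments with maximum total agreement.
#'
#' @param result A `ClusterResult`.
#' @param labels True class labels, one per clustered point.
#' @return Named character vector (cluster index -> class), with attribute
#'   `"agreement"` (fraction of points whose mapped cluster class matches
#'   their label).
#' @export
map_clusters_to_classes <- function(result, labels) {
  stopifnot(length(labels) == length(result$assignments))
  K <- result$K
  classes <- sort(unique(labels))
  tab <- table(factor(result$assignments, levels = seq_len(K)),
               factor(labels, levels = classes))
  majority <- classes[max.col(tab, ties.method = "first")]
  agreement_of <- function(map) sum(tab[cbind(seq_len(K), match(map, classes))])
  if (anyDuplicated(majority) && K == length(classes)) {
    perms <- permutations_of(classes)
    scores <- vapply(perms, agreement_of, numeric(1))
    majority <- perms[[which.max(scores)]]
  }
  if (length(unique(labels)) == 1)
    warning("all samples share one class; cluster map is degenerate",
            call. = FALSE)
  structure(stats::setNames(majority, as.character(seq_len(K))),
            agreement = agreement_of(majority) / length(labels))
}

# All permutations of a small vector (used for K <= 6).
permutations_of <- function(x) {
  n <- length(x)
  if (n == 1) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

#' Pairwise Euclidean distances between class-mapped centroids
#'
#' @param result A `ClusterResult`.
#' @param label_map Bijective cluster -> class map from
#'   [map_clusters_to_classes()].
#' @return Named numeric vector of distances for every unordered class pair
#'   (names like `"fibroblast-hippocampus"`, alphabetical within the pair).
#' @export
centroid_distances <- function(result, label_map) {
  if (anyDuplicated(label_map))
    stop_cp("label map is not bijective; centroid distances undefined")
  classes <- sort(unname(label_map))
  cent <- result$centroids[match(classes, label_map[as.character(seq_len(result$K))]), ,
                           drop = FALSE]
  out <- numeric(0)
  for (i in seq_len(length(classes) - 1)) {
    for (j in (i + 1):length(classes)) {
      out[paste(classes[i], classes[j], sep = "-")] <-
        euclidean_distance(cent[i, ], cent[j, ])
    }
  }
  out
}

#' Embed samples in the 2-D latent space and cluster them
#'
#' Trains a bottleneck-2 autoencoder on the pooled samples, encodes them,
#' runs K-means with K equal to the number of classes, maps clusters to
#' classes by majority and computes the pairwise centroid distances. The
#' embedding is used for visualization and separation measurement only --
#' classification always operates on the full-dimensional samples.
#'
#' @param X Preprocessed sample matrix (windows from >= 2 classes).
#' @param labels Class label per row.
#' @param hp A [train_hyperparams()].
#' @param hidden Encoder hidden widths.
#' @param seed Seed for the K-means restarts.
#' @param n_init K-means restarts.
#' @return List with `embedding` (n x 2 latent coordinates), `clusters`
#'   (`ClusterResult`), `label_map`, `agreement`, `distances`.
#' @export
embed_and_cluster <- function(X, labels, hp = train_hyperparams(),
                              hidden = c(100, 50), seed = 1, n_init = 10) {
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop_cp("need samples from >= 2 classes to measure separation")
  spec <- autoencoder_spec(input_dim = ncol(X), hidden = hidden, bottleneck = 2)
  model <- train_autoencoder(X, spec, hp)
  emb <- encode(model, X)
  cl <- kmeans_lloyd(emb, K = length(classes), seed = seed, n_init = n_init)
  map <- map_clusters_to_classes(cl, labels)
  dists <- centroid_distances(cl, map)
  list(embedding = emb, clusters = cl, label_map = map,
       agreement = attr(map, "agreement"), distances = dists,
       model = model)
}
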