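#' Preprocessing configuration
#'
#' Bundles the windowing / dimensionality-reduction / scaling parameters used
#' throughout the pipeline: raw windows of `window_length` points taken every
#' `stride` points, compressed to `paa_length` points by piecewise aggregate
#' approximation, then min-max scaled to \[0, 1\].
#'
#' @param window_length Window length l in points.
#' @param stride Stride r between window starts in points.
#' @param paa_length Reduced length w; must divide `window_length`.
#' @param normalization_scope `"per_fold_train"` (fit the \[0,1\] map on the
#'   fold's training windows only, apply it unchanged to the test windows,
#'   clipping) or `"joint"` (fit on train and test pooled; the naive
#'   all-data-normalization reading).
#' @return A `PreprocessConfig`.
#' @export
preprocess_config <- function(window_length = 1000, stride = 200,
                              paa_length = 200,
                              normalization_scope = c("per_fold_train", "joint")) {
  normalization_scope <- match.arg(normalization_scope)
  stopifnot(window_length >= 1, stride >= 1, paa_length >= 1)
  if (paa_length > window_length) stop_cp("paa_length must be <= window_length")
  if (stride > window_length) stop_cp("stride must be <= window_length")
  if (window_length %% paa_length != 0)
    stop_cp("window_length must be divisible by paa_length (equal frames)")
  structure(list(window_length = as.integer(window_length),
                 stride = as.integer(stride),
                 paa_length = as.integer(paa_length),
                 normalization_scope = normalization_scope),
            class = "PreprocessConfig")
}

#' Truncate recordings to the shortest length
#'
#' Cuts every trace to the prefix of length equal to the shortest trace, so
#' every recording later contributes the same number of windows (avoids class
#' imbalance).
#'
#' @param recordings Named list of `Recording`s (>= 1).
#' @return The recordings, truncated, in the original order.
#' @export
truncate_to_shortest <- function(recordings) {
  stopifnot(length(recordings) >= 1)
  n_min <- min(vapply(recordings, function(r) length(r$trace), integer(1)))
  lapply(recordings, function(r) { r$trace <- r$trace[seq_len(n_min)]; r })
}

#' Split a trace into strided windows
#'
#' Windows of length `l` starting at 0-based offsets `0, r, 2r, ...`;
#' exactly `floor((L - l) / r)` windows are emitted for a trace of length `L`.
#'
#' @param trace Numeric vector.
#' @param l Window length.
#' @param r Stride.
#' @return Matrix with one window per row and the 0-based start offsets as an
#'   attribute `"offsets"`; zero rows (with a warning) when `L < l`.
#' @export
split_windows <- function(trace, l, r) {
  L <- length(trace)
  if (L < l) {
    warning(sprintf("trace length %d < window length %d: no windows", L, l),
            call. = FALSE)
    out <- matrix(numeric(0), nrow = 0, ncol = l)
    attr(out, "offsets") <- integer(0)
    return(out)
  }
  n_win <- (L - l) %/% r
  offsets <- (seq_len(n_win) - 1L) * r
  out <- matrix(0, nrow = n_win, ncol = l)
  for (i in seq_len(n_win)) {
    out[i, ] <- trace[(offsets[i] + 1L):(offsets[i] + l)]
  }
  attr(out, "offsets") <- offsets
  out
}

#' Piecewise aggregate approximation
#'
#' Reduces each length-`l` window to `w` points by dividing it into `w`
#' equal frames and replacing each frame by its mean.
#'
#' @param x Numeric vector of length divisible by `w`, or a matrix whose rows
#'   are such vectors.
#' @param w Reduced length.
#' @return Vector of length `w`, or matrix with `w` columns.
#' @export
paa <- function(x, w) {
  if (is.matrix(x)) {
    l <- ncol(x)
    if (l %% w != 0) stop_cp("window length %d not divisible by w = %d", l, w)
    frame <- l %/% w
    # row-wise frame means via a single matrix product
    M <- matrix(0, nrow = l, ncol = w)
    for (j in seq_len(w)) M[((j - 1) * frame + 1):(j * frame), j] <- 1 / frame
    return(x %*% M)
  }
  l <- length(x)
  if (l %% w != 0) stop_cp("window length %d not divisible by w = %d", l, w)
  frame <- l %/% w
  colMeans(matrix(x, nrow = frame, ncol = w))
}

#' Fit-and-apply min-max scaling to [0, 1]
#'
#' The affine map `(x - min) / (max - min)` is fitted on the pooled training
#' values and applied unchanged to the test values; test values falling
#' outside \[0, 1\] are clipped and counted.
#'
#' @param train Numeric matrix of training samples (rows).
#' @param test Optional numeric matrix of test samples.
#' @return List with `train`, `test` (scaled), `min`, `max`, and
#'   `n_clipped` (test values clipped).
#' @export
minmax_scale <- function(train, test = NULL) {
  stopifnot(is.matrix(train), nrow(train) > 0)
  lo <- min(train); hi <- max(train)
  if (hi <= lo) stop_cp("constant training data: min-max scaling undefined")
  sc <- function(x) (x - lo) / (hi - lo)
  train_s <- sc(train)
  test_s <- NULL
  n_clipped <- 0L
  if (!is.null(test)) {
    test_s <- sc(test)
    n_clipped <- sum(test_s < 0 | test_s > 1)
    test_s <- clamp(test_s, 0, 1)
  }
  list(train = train_s, test = test_s, min = lo, max = hi,
       n_clipped = n_clipped)
}

#' Enumerate leave-one-recording-per-class cross-validation folds
#'
#' One fold per element of the Cartesian product of per-class recording
#' choices: in each fold exactly one recording of every class is the test
#' set and all remaining recordings form the training set. Folds are ordered
#' lexicographically by the test recording ids.
#'
#' @param recordings Named list of `Recording`s (a single potential).
#' @return List of `FoldSplit`s: each a list with `fold_id`,
#'   `test_recordings`, `train_recordings`.
#' @export
make_cv_folds <- function(recordings) {
  labels <- vapply(recordings, function(r) r$cell_label, character(1))
  ids <- vapply(recordings, function(r) r$recording_id, character(1))
  by_class <- split(unname(ids), labels)
  for (cl in names(by_class)) {
    if (length(by_class[[cl]]) < 2)
      stop_cp("class '%s' has fewer than 2 recordings: cross-validation impossible", cl)
    by_class[[cl]] <- sort(by_class[[cl]])
  }
  by_class <- by_class[sort(names(by_class))]
  grid <- expand.grid(rev(by_class), stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(by_class)), drop = FALSE]  # first class varies slowest
  folds <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    test_ids <- unname(unlist(grid[i, ]))
    folds[[i]] <- structure(list(
      fold_id = sprintf("fold%03d", i),
      test_recordings = test_ids,
      train_recordings = setdiff(unname(ids), test_ids)
    ), class = "FoldSplit")
  }
  folds
}

#' Preprocess one cross-validation fold
#'
#' Runs the full chain on the fold's recordings: truncate all (train and
#' test) to the shortest common length, split into strided windows, compress
#' by PAA, then min-max scale according to the config's normalization scope.
#'
#' @param fold A `FoldSplit` from [make_cv_folds()].
#' @param recordings Named list of `Recording`s covering the fold.
#' @param config A `PreprocessConfig`.
#' @return List with `train` / `test` (scaled sample matrices, one window per
#'   row), `train_meta` / `test_meta` (data frames: recording_id, cell_label,
#'   potential, offset), `truncation_length`, `scaling` (min, max,
#'   n_clipped).
#' @export
preprocess_fold <- function(fold, recordings, config = preprocess_config()) {
  all_ids <- c(fold$train_recordings, fold$test_recordings)
  missing <- setdiff(all_ids, names(recordings))
  if (length(missing) > 0)
    stop_cp("fold references unknown recordings: %s", paste(missing, collapse = ", "))
  recs <- truncate_to_shortest(recordings[all_ids])
  trunc_len <- length(recs[[1]]$trace)
  build <- function(ids) {
    mats <- list(); metas <- list()
    for (id in ids) {
      r <- recs[[id]]
      wins <- split_windows(r$trace, config$window_length, config$stride)
      if (nrow(wins) == 0) next
      reduced <- paa(wins, config$paa_length)
      mats[[id]] <- reduced
      metas[[id]] <- data.frame(
        recording_id = id, cell_label = r$cell_label, potential = r$potential,
        offset = attr(wins, "offsets"), stringsAsFactors = FALSE)
    }
    if (length(mats) == 0)
      stop_cp("no windows produced (recordings shorter than the window length?)")
    list(x = do.call(rbind, mats), meta = do.call(rbind, metas))
  }
  tr <- build(fold$train_recordings)
  te <- build(fold$test_recordings)
  if (config$normalization_scope == "per_fold_train") {
    sc <- minmax_scale(tr$x, te$x)
  } else {
    pooled <- minmax_scale(rbind(tr$x, te$x))
    sc <- list(train = pooled$train[seq_len(nrow(tr$x)), , drop = FALSE],
               test = pooled$train[nrow(tr$x) + seq_len(nrow(te$x)), , drop = FALSE],
               min = pooled$min, max = pooled$max, n_clipped = 0L)
  }
  rownames(tr$meta) <- NULL; rownames(te$meta) <- NULL
  list(train = sc$train, test = sc$test,
       train_meta = tr$meta, test_meta = te$meta,
       truncation_length = trunc_len,
       scaling = list(min = sc$min, max = sc$max, n_clipped = sc$n_clipped,
                      scope = config$normalization_scope))
}

#' Preprocess a set of recordings as one pooled sample matrix
#'
#' The same truncate / window / PAA / scale chain as [preprocess_fold()], but
#' without a train/test split: scaling is fitted on all windows pooled. Used
#' for anomaly scoring and single-shot latent embedding.
#'
#' @param recordings Named list of `Recording`s.
#' @param config A `PreprocessConfig`.
#' @return List with `x` (scaled window matrix), `meta` (provenance data
#'   frame) and `scaling`.
#' @export
preprocess_pooled <- function(recordings, config = preprocess_config()) {
  recs <- truncate_to_shortest(recordings)
  mats <- list(); metas <- list()
  for (r in recs) {
    wins <- split_windows(r$trace, config$window_length, config$stride)
    if (nrow(wins) == 0) next
    reduced <- paa(wins, config$paa_length)
    mats[[r$recording_id]] <- reduced
    metas[[r$recording_id]] <- data.frame(
      recording_id = r$recording_id, cell_label = r$cell_label,
      potential = r$potential, offset = attr(wins, "offsets"),
      stringsAsFactors = FALSE)
  }
  if (length(mats) == 0) stop_cp("no windows produced")
  sc <- minmax_scale(do.call(rbind, mats))
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  list(x = sc$train, meta = meta,
       scaling = list(min = sc$min, max = sc$max))
}
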