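#' Reconstruction-error scores for one category of recordings
#'
#' Trains a single bottleneck-2 autoencoder on all preprocessed windows of a
#' category (one cell type at one potential), including any suspect
#' recordings, then scores each recording by the mean reconstruction error J
#' over its own windows. Recordings whose gating deviates from the category's
#' dominant pattern reconstruct poorly and receive large scores.
#'
#' @param recordings Named list of `Recording`s from one (cell type,
#'   potential) category; >= 3 recordings.
#' @param config A [preprocess_config()].
#' @param hp A [train_hyperparams()].
#' @param hidden Encoder hidden widths.
#' @return List with `scores` (named numeric, one per recording), `model`
#'   (the trained autoencoder) and `windows` (the pooled preprocessed data).
#' @export
score_category <- function(recordings, config = preprocess_config(),
                           hp = train_hyperparams(), hidden = c(100, 50)) {
  if (length(recordings) < 3)
    stop_cp("need >= 3 recordings in a category to score anomalies")
  # canonical order: scores must not depend on how recordings were listed
  recordings <- recordings[sort(names(recordings))]
  pooled <- preprocess_pooled(recordings, config)
  spec <- autoencoder_spec(input_dim = ncol(pooled$x), hidden = hidden,
                           bottleneck = 2)
  model <- train_autoencoder(pooled$x, spec, hp)
  errs <- reconstruction_error(model, pooled$x, per_sample = TRUE)
  scores <- tapply(errs, pooled$meta$recording_id, mean)
  scores <- stats::setNames(as.numeric(scores), names(scores))
  list(scores = scores, model = model, windows = pooled)
}

#' Flag outlier recordings from their reconstruction-error scores
#'
#' A recording is flagged when its modified z-score
#' `(score - median) / (1.4826 * MAD)` exceeds `threshold` (one-sided: only
#' anomalously LARGE reconstruction errors mark outliers). Because
#' reconstruction-error scores are positive and scale with the category's
#' signal variance, the scale estimate is floored at `scale_floor_frac`
#' times the median score: with a handful of recordings per category the MAD
#' can collapse on benignly tight scores and turn percent-level fluctuations
#' into huge z-values, while genuine anomalies deviate by large fractions of
#' the typical score. When the MAD is zero but scores differ, an IQR rule
#' (`score > Q3 + 1.5 IQR`) is used instead and the fallback is recorded.
#' Identical scores never flag.
#'
#' @param scores Named numeric vector of per-recording scores (>= 3).
#' @param threshold Modified z-score threshold.
#' @param method Flagging rule; only `"robust_z"` is implemented.
#' @param scale_floor_frac Lower bound on the robust scale, as a fraction of
#'   the median score.
#' @return Character vector of flagged recording ids, with attributes
#'   `"zscores"` and `"rule"`.
#' @export
flag_outliers <- function(scores, threshold = 3.5, method = "robust_z",
                          scale_floor_frac = 0.05) {
  stopifnot(method == "robust_z", length(scores) >= 3)
  med <- stats::median(scores)
  madn <- stats::mad(scores)  # 1.4826 * MAD
  scale_floor <- scale_floor_frac * abs(med)
  if (all(scores == scores[1])) {
    out <- character(0)
    z <- rep(0, length(scores))
    rule <- "robust_z"
  } else if (madn == 0 && scale_floor == 0) {
    q <- stats::quantile(scores, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    cut <- q[2] + 1.5 * iqr
    out <- names(scores)[scores > cut & scores > med]
    z <- (scores - med)
    rule <- "iqr_fallback"
  } else {
    z <- (scores - med) / max(madn, scale_floor)
    out <- names(scores)[z > threshold]
    rule <- "robust_z"
  }
  structure(out, zscores = stats::setNames(as.numeric(z), names(scores)),
            rule = rule, threshold = threshold)
}

#' Confirm a suspected outlier with a bottleneck sweep
#'
#' Reproduces the diagnostic comparison of reconstruction error versus
#' bottleneck dimension for a candidate-outlier recording against a typical
#' one: each recording's windows are preprocessed separately and swept over
#' the requested bottleneck dimensions.
#'
#' @param candidate,typical `Recording`s.
#' @param dims Bottleneck dimensions (nonempty).
#' @param config A [preprocess_config()].
#' @param hp A [train_hyperparams()].
#' @return List with `candidate`, `typical` (data frames dim, J) and
#'   `verdict` (`TRUE` when the candidate's J exceeds the typical's at every
#'   dimension).
#' @export
confirm_outlier <- function(candidate, typical, dims,
                            config = preprocess_config(),
                            hp = train_hyperparams()) {
  if (length(dims) == 0) stop_cp("dims must be nonempty")
  sweep_rec <- function(rec) {
    pooled <- preprocess_pooled(stats::setNames(list(rec), rec$recording_id),
                                config)
    bottleneck_sweep(pooled$x, dims, hp = hp)
  }
  cand <- sweep_rec(candidate)
  typ <- sweep_rec(typical)
  list(candidate = cand, typical = typ,
       verdict = all(cand$J > typ$J))
}

#' Detect anomalous recordings across all categories
#'
#' Splits the recordings into (cell type, potential) categories, scores each
#' category with [score_category()] and flags outliers with
#' [flag_outliers()].
#'
#' @param recordings Named list of `Recording`s.
#' @param config A [preprocess_config()].
#' @param hp A [train_hyperparams()]; the seed is re-derived per category so
#'   categories are independent but reproducible.
#' @param threshold Modified z-score threshold for [flag_outliers()].
#' @param hidden Encoder hidden widths.
#' @return An `AnomalyReport`: list with `categories` (per-category scores,
#'   flags, rule) and `flagged` (all flagged ids).
#' @export
detect_anomalies <- function(recordings, config = preprocess_config(),
                             hp = train_hyperparams(), threshold = 3.5,
                             hidden = c(100, 50)) {
  groups <- group_recordings(recordings)
  categories <- list()
  flagged <- character(0)
  for (i in seq_along(groups)) {
    key <- names(groups)[i]
    ids <- groups[[i]]
    hp_cat <- hp
    hp_cat$seed <- derive_seed(hp$seed, i)
    sc <- score_category(recordings[ids], config, hp_cat, hidden)
    fl <- flag_outliers(sc$scores, threshold = threshold)
    categories[[key]] <- list(category = key, scores = sc$scores,
                              flagged = as.character(fl),
                              zscores = attr(fl, "zscores"),
                              rule = attr(fl, "rule"),
                              threshold = threshold)
    flagged <- c(flagged, as.character(fl))
  }
  structure(list(categories = categories, flagged = flagged),
            class = "AnomalyReport")
}

#' @export
print.AnomalyReport <- function(x, ...) {
  cat(sprintf("<AnomalyReport> %d categories, %d flagged recording(s)\n",
              length(x$categories), length(x$flagged)))
  if (length(x$flagged) > 0) cat("  flagged:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Remove flagged recordings from a dataset
#'
#' @param recordings Named list of `Recording`s.
#' @param report An `AnomalyReport` (or character vector of ids to drop).
#' @return List with `recordings` (cleaned) and `audit` (data frame of
#'   removals: recording_id, category, score). Errors when a removal would
#'   leave any class at any potential with fewer than 2 recordings.
#' @export
filter_dataset <- function(recordings, report) {
  flagged <- if (inherits(report, "AnomalyReport")) report$flagged
             else as.character(report)
  keep <- setdiff(names(recordings), flagged)
  cleaned <- recordings[keep]
  groups <- group_recordings(cleaned)
  too_small <- names(groups)[vapply(groups, length, integer(1)) < 2]
  if (length(too_small) > 0)
    stop_cp("anomaly filtering would leave <2 recordings in: %s",
            paste(too_small, collapse = ", "))
  audit <- data.frame(recording_id = character(0), category = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (inherits(report, "AnomalyReport") && length(flagged) > 0) {
    rows <- list()
    for (cat in report$categories) {
      for (id in cat$flagged) {
        rows[[id]] <- data.frame(recording_id = id, category = cat$category,
                                 score = unname(cat$scores[id]),
                                 stringsAsFactors = FALSE)
      }
    }
    audit <- do.call(rbind, rows)
    rownames(audit) <- NULL
  } else if (length(flagged) > 0) {
    audit <- data.frame(recording_id = flagged, category = NA_character_,
                        score = NA_real_, stringsAsFactors = FALSE)
  }
  list(recordings = cleaned, audit = audit)
}
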