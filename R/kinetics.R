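#' Threshold current from the amplitude density
#'
#' Locates the threshold current (TC) separating conducting from
#' non-conducting samples. The absolute current amplitudes are kernel-density
#' estimated (Epanechnikov kernel) on a logarithmic grid; on each side of the
#' valley between the two amplitude modes, the widest contiguous stretch
#' where log-density is locally linear in log-amplitude (rolling linear fit
#' with R^2 at or above `r2_min`: the "power-law" stretch) is fitted by least
#' squares, and the TC is the abscissa where the two fitted lines intersect.
#'
#' When no adequate power-law stretch exists on one of the sides (e.g. for
#' nearly noise-free two-level traces whose density collapses to spikes), the
#' estimate falls back to the geometric midpoint of the two modes
#' (`method = "midpoint"` in the result); the fallback is recorded, not
#' silent.
#'
#' @param recording A `Recording` (or numeric trace) with at least 1000
#'   samples representing both conductance levels.
#' @param bw Bandwidth for the KDE of log-amplitudes (numeric, or `"nrd0"`
#'   for Silverman's rule).
#' @param grid_n KDE grid size.
#' @param r2_min Rolling-fit R^2 required for a stretch to count as power law.
#' @param min_window Minimum stretch width in grid points.
#' @return A `ThresholdEstimate`: list with `tc` (pA), `kde` (data frame
#'   `amplitude`, `density`), `segments` (per-side fitted slope/intercept in
#'   log-log coordinates and grid interval), `method` ("power_law" or
#'   "midpoint"), `metadata` (bandwidth, grid size, mode locations).
#' @export
estimate_threshold_current <- function(recording, bw = "nrd0", grid_n = 512,
                                       r2_min = 0.98, min_window = 5) {
  trace <- if (inherits(recording, "Recording")) recording$trace else recording
  if (length(trace) < 1000) stop_cp("need >= 1000 samples for a threshold estimate")
  a <- abs(trace)
  amax <- max(a); amin <- min(a)
  if (amax <= 0) stop_cp("all-zero trace")
  offset <- (amax - amin) / grid_n / 2  # guards log(0)
  if (offset <= 0) offset <- amax * 1e-6
  x <- log(a + offset)
  dens <- stats::density(x, bw = bw, kernel = "epanechnikov", n = grid_n)
  gx <- dens$x
  gy <- dens$y
  # prominent local maxima of the density
  floor_y <- max(gy) * 1e-4
  is_max <- c(FALSE, diff(sign(diff(gy))) < 0, FALSE) & gy > floor_y
  # include plateau ends
  peaks <- which(is_max)
  if (gy[1] > gy[2] && gy[1] > floor_y) peaks <- c(1L, peaks)
  if (gy[grid_n] > gy[grid_n - 1] && gy[grid_n] > floor_y)
    peaks <- c(peaks, grid_n)
  if (length(peaks) < 2)
    stop_cp("cannot separate states: amplitude density is unimodal")
  # the two modes: leftmost and rightmost prominent peaks after keeping the
  # two highest-density peaks that are well separated
  ord <- peaks[order(gy[peaks], decreasing = TRUE)]
  m1 <- ord[1]
  m2 <- NA_integer_
  for (p in ord[-1]) {
    if (abs(gx[p] - gx[m1]) > 4 * dens$bw) { m2 <- p; break }
  }
  if (is.na(m2))
    stop_cp("cannot separate states: amplitude density is effectively unimodal")
  lo <- min(m1, m2); hi <- max(m1, m2)
  valley <- lo + which.min(gy[lo:hi]) - 1L
  ly <- log(pmax(gy, max(gy) * 1e-12))

  # the Epanechnikov kernel has compact support, so the inter-modal gap can
  # hold exact zeros; fit the flanks only where the density is genuinely
  # positive
  flo <- max(gy) * 1e-9
  zero_left <- which(gy[lo:valley] <= flo)
  left_hi <- if (length(zero_left)) lo + min(zero_left) - 2L else valley
  zero_right <- which(gy[valley:hi] <= flo)
  right_lo <- if (length(zero_right)) valley + max(zero_right) else valley

  seg_left <- if (left_hi > lo)
    widest_linear_window(gx, ly, lo, left_hi, r2_min, min_window) else NULL
  seg_right <- if (hi > right_lo)
    widest_linear_window(gx, ly, right_lo, hi, r2_min, min_window) else NULL
  method <- "power_law"
  tc <- NA_real_
  # the left flank must decay and the right flank rise for the intersection
  # to mark the inter-modal threshold
  if (!is.null(seg_left) && !is.null(seg_right) &&
      seg_left$slope < 0 && seg_right$slope > 0 &&
      abs(seg_left$slope - seg_right$slope) > 1e-12) {
    x_star <- (seg_right$intercept - seg_left$intercept) /
      (seg_left$slope - seg_right$slope)
    if (x_star > gx[lo] && x_star < gx[hi]) {
      tc <- exp(x_star) - offset
    }
  }
  if (!is.finite(tc) || tc <= amin || tc >= amax) {
    method <- "midpoint"
    tc <- exp((gx[lo] + gx[hi]) / 2) - offset
  }
  if (!(tc > amin && tc < amax))
    stop_cp("threshold estimate (%.3g pA) lies outside the amplitude range", tc)
  structure(list(
    tc = tc,
    kde = data.frame(amplitude = exp(gx) - offset, density = gy),
    segments = list(left = seg_left, right = seg_right),
    method = method,
    metadata = list(bandwidth = dens$bw, grid_n = grid_n, offset = offset,
                    modes = exp(gx[c(lo, hi)]) - offset, r2_min = r2_min)
  ), class = "ThresholdEstimate")
}

# Widest contiguous window within grid indices [from, to] on which y ~ x is
# linear with R^2 >= r2_min. Uses cumulative sums for O(1) window statistics.
widest_linear_window <- function(x, y, from, to, r2_min, min_window) {
  idx <- from:to
  n <- length(idx)
  if (n < min_window) return(NULL)
  xs <- x[idx]; ys <- y[idx]
  cx <- cumsum(xs); cy <- cumsum(ys)
  cxx <- cumsum(xs^2); cyy <- cumsum(ys^2); cxy <- cumsum(xs * ys)
  span_sum <- function(cs, a, b) cs[b] - if (a > 1) cs[a - 1] else 0
  best <- NULL
  for (w in seq(n, min_window)) {
    for (a in seq_len(n - w + 1)) {
      b <- a + w - 1
      m <- w
      sx <- span_sum(cx, a, b); sy <- span_sum(cy, a, b)
      sxx <- span_sum(cxx, a, b); syy <- span_sum(cyy, a, b)
      sxy <- span_sum(cxy, a, b)
      vx <- sxx - sx^2 / m
      vy <- syy - sy^2 / m
      cvxy <- sxy - sx * sy / m
      if (vx <= 0 || vy <= 1e-12) next  # a flat stretch is not a power law
      r2 <- cvxy^2 / (vx * vy)
      if (r2 >= r2_min) {
        slope <- cvxy / vx
        intercept <- (sy - slope * sx) / m
        best <- list(slope = slope, intercept = intercept,
                     interval = c(x[idx[a]], x[idx[b]]),
                     grid_index = c(idx[a], idx[b]), r2 = r2, width = w)
        return(best)
      }
    }
  }
  best
}

#' @export
print.ThresholdEstimate <- function(x, ...) {
  cat(sprintf("<ThresholdEstimate> TC = %.4g pA (%s; bw = %.3g, grid %d)\n",
              x$tc, x$method, x$metadata$bandwidth, x$metadata$grid_n))
  invisible(x)
}

#' Open-state probability of a recording
#'
#' Fraction of samples whose absolute current exceeds the threshold current;
#' a per-sample census, invariant to sign flips and to sample order.
#'
#' @param recording A `Recording` or numeric trace.
#' @param tc Threshold current in pA (e.g. from
#'   [estimate_threshold_current()]); must lie within the amplitude range.
#' @return p_op in \[0, 1\].
#' @export
open_probability <- function(recording, tc) {
  trace <- if (inherits(recording, "Recording")) recording$trace else recording
  a <- abs(trace)
  if (!(tc >= min(a) && tc <= max(a)))
    stop_cp("tc = %g pA outside amplitude range [%g, %g]", tc, min(a), max(a))
  mean(a > tc)
}

#' Fit a Boltzmann activation curve
#'
#' Least-squares fit of the sigmoidal voltage dependence
#' `p_op(U) = p_max / (1 + exp(-(U - v_half) / slope))` to per-potential open
#' probabilities, via Levenberg-Marquardt.
#'
#' @param points Data frame with columns `potential` (mV) and `p_op`;
#'   optionally `sd` (across replicate recordings, carried through).
#' @param p_max_upper Upper bound for `p_max` (probability cap).
#' @return An `ActivationCurve`: list with `points`, `fit`
#'   (`v_half`, `slope`, `p_max`), `residual_ss` and the `nls` object.
#' @export
fit_activation_curve <- function(points, p_max_upper = 1) {
  stopifnot(is.data.frame(points), all(c("potential", "p_op") %in% names(points)))
  pts <- points[is.finite(points$p_op), , drop = FALSE]
  if (length(unique(pts$potential)) < 4)
    stop_cp("need >= 4 distinct potentials to fit an activation curve")
  if (any(pts$p_op < 0 | pts$p_op > 1)) stop_cp("p_op values must lie in [0, 1]")
  if (stats::sd(pts$p_op) < 1e-3)
    stop_cp("degenerate activation data: p_op is constant, slope unidentifiable")
  p_max0 <- clamp(max(pts$p_op), 0.05, p_max_upper)
  v_half0 <- pts$potential[which.min(abs(pts$p_op - p_max0 / 2))]
  # rising curve assumed (depolarization activates); slope > 0
  fit <- tryCatch(
    minpack.lm::nlsLM(
      p_op ~ p_max / (1 + exp(-(potential - v_half) / slope)),
      data = pts,
      start = list(p_max = p_max0, v_half = v_half0, slope = 10),
      lower = c(p_max = 1e-3, v_half = -500, slope = 0.1),
      upper = c(p_max = p_max_upper, v_half = 500, slope = 1000),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop_cp("activation fit failed: %s (start: p_max=%g, v_half=%g, slope=10)",
                                conditionMessage(e), p_max0, v_half0))
  cf <- stats::coef(fit)
  structure(list(points = pts,
                 fit = c(v_half = unname(cf["v_half"]),
                         slope = unname(cf["slope"]),
                         p_max = unname(cf["p_max"])),
                 residual_ss = sum(stats::resid(fit)^2),
                 model = fit),
            class = "ActivationCurve")
}

#' @export
print.ActivationCurve <- function(x, ...) {
  cat(sprintf("<ActivationCurve> V1/2 = %.2f mV, slope = %.2f mV, p_max = %.3f (RSS %.2e, %d points)\n",
              x$fit[["v_half"]], x$fit[["slope"]], x$fit[["p_max"]],
              x$residual_ss, nrow(x$points)))
  invisible(x)
}

#' Predict from a fitted activation curve
#'
#' @param object An `ActivationCurve`.
#' @param potential Potentials (mV) at which to evaluate.
#' @param ... Unused.
#' @return Predicted p_op values.
#' @export
predict.ActivationCurve <- function(object, potential, ...) {
  f <- object$fit
  f[["p_max"]] / (1 + exp(-(potential - f[["v_half"]]) / f[["slope"]]))
}

#' Per-recording kinetic summary table
#'
#' Runs [estimate_threshold_current()] and [open_probability()] on every
#' recording and tabulates the results.
#'
#' @param recordings Named list of `Recording`s.
#' @param ... Passed to [estimate_threshold_current()].
#' @return Data frame with recording_id, cell_label, potential_mV, tc_pA,
#'   p_op, threshold_method.
#' @export
kinetic_summary <- function(recordings, ...) {
  rows <- lapply(recordings, function(rec) {
    th <- estimate_threshold_current(rec, ...)
    data.frame(recording_id = rec$recording_id, cell_label = rec$cell_label,
               potential_mV = rec$potential, tc_pA = th$tc,
               p_op = open_probability(rec, th$tc),
               threshold_method = th$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
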