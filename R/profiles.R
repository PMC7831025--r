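#' Cell profile: one class of channel kinetics across the six potentials
#'
#' A cell profile maps each pipette potential of the experimental design to a
#' gating scheme and records the designed activation-curve parameters
#' (`v_half`, `slope`, `p_max`) of the stationary open probability.
#'
#' @param label Class name (e.g. "endothelium").
#' @param scheme A `GatingScheme` shared by all potentials, or a named list of
#'   schemes keyed by potential (names like "-60", "20").
#' @param activation_params Numeric vector `c(v_half=, slope=, p_max=)`
#'   describing the designed p_op(U_m) curve.
#' @param potentials Pipette potentials (mV) the profile must cover.
#' @return A `CellProfile`.
#' @export
cell_profile <- function(label, scheme, activation_params,
                         potentials = c(-60, -40, -20, 20, 40, 60)) {
  stopifnot(length(potentials) >= 1)
  if (inherits(scheme, "GatingScheme")) {
    schemes <- stats::setNames(rep(list(scheme), length(potentials)),
                               as.character(potentials))
  } else {
    schemes <- scheme
    missing <- setdiff(as.character(potentials), names(schemes))
    if (length(missing) > 0)
      stop_cp("profile '%s' lacks schemes for potentials: %s", label,
              paste(missing, collapse = ", "))
  }
  p_max <- activation_params[["p_max"]]
  if (!(p_max > 0 && p_max <= 1)) stop_cp("p_max must be in (0, 1]")
  structure(list(label = label,
                 scheme_per_potential = schemes,
                 activation_params = activation_params,
                 potentials = potentials),
            class = "CellProfile")
}

#' @export
print.CellProfile <- function(x, ...) {
  ap <- x$activation_params
  cat(sprintf("<CellProfile %s> V1/2 = %g mV, slope = %g mV, p_max = %g; %d potentials\n",
              x$label, ap[["v_half"]], ap[["slope"]], ap[["p_max"]],
              length(x$potentials)))
  invisible(x)
}

# Scheme a profile uses at a given potential.
scheme_for <- function(profile, potential) {
  s <- profile$scheme_per_potential[[as.character(potential)]]
  if (is.null(s)) stop_cp("profile '%s' has no scheme at %g mV",
                          profile$label, potential)
  s
}

#' Designed stationary open probability of a profile
#'
#' @param profile A `CellProfile`.
#' @param potential Pipette potential (mV).
#' @return Stationary conducting-state probability of the profile's scheme at
#'   that potential.
#' @export
profile_open_probability <- function(profile, potential) {
  stationary_open_probability(scheme_for(profile, potential), potential)
}

#' Default tissue profiles
#'
#' Three two-state profiles sharing the 300 pS conductance but differing in
#' half-activation potential, activation slope and dwell-time scale, emulating
#' channels whose open probabilities are similar at strongly polarized
#' potentials while the fine structure of gating (dwell times) differs:
#' \itemize{
#'   \item endothelium: V1/2 = +5 mV, slope 12 mV, rate scale 500 s^-1
#'     (fast gating, right-shifted activation);
#'   \item fibroblast: V1/2 = -20 mV, slope 14 mV, rate scale 200 s^-1;
#'   \item hippocampus: V1/2 = -30 mV, slope 10 mV, rate scale 100 s^-1
#'     (slow gating, left-shifted activation).
#' }
#'
#' @param noise_sd Gaussian noise SD in pA.
#' @param filter_corner Low-pass corner in Hz (`NA` = no filtering).
#' @param p_max Maximal open probability; the default 0.95 keeps brief
#'   closures even at saturating depolarization, as patch recordings show.
#' @return List of three `CellProfile`s.
#' @export
default_profiles <- function(noise_sd = 0.8, filter_corner = NA_real_,
                             p_max = 0.95) {
  mk <- function(label, v_half, slope, rate_scale) {
    cell_profile(
      label,
      two_state_scheme(paste0(label, "_2state"), v_half = v_half,
                       slope = slope, rate_scale = rate_scale, p_max = p_max,
                       noise_sd = noise_sd, filter_corner = filter_corner),
      activation_params = c(v_half = v_half, slope = slope, p_max = p_max))
  }
  list(endothelium = mk("endothelium", 5, 12, 500),
       fibroblast  = mk("fibroblast", -20, 14, 200),
       hippocampus = mk("hippocampus", -30, 10, 100))
}

#' Well-separated tissue profiles
#'
#' Three profiles with widely separated, nearly voltage-flat open
#' probabilities (about 0.12 / 0.5 / 0.88) and distinct, fast (flicker-range)
#' dwell-time scales: mean dwells of roughly 0.2-3 ms, so each frame of the
#' piecewise aggregate approximation averages over several gating events and
#' window vectors concentrate near the class occupancy level. Used as the
#' strongly discriminable fixture for end-to-end classification checks.
#'
#' @inheritParams default_profiles
#' @return List of three `CellProfile`s.
#' @export
well_separated_profiles <- function(noise_sd = 0.8, filter_corner = NA_real_) {
  mk <- function(label, p_open, rate_scale) {
    # near-constant p_op: a very shallow Boltzmann centred so sigma(0) = p_open
    slope <- 2000
    v_half <- -slope * log(p_open / (1 - p_open))
    cell_profile(
      label,
      two_state_scheme(paste0(label, "_flat"), v_half = v_half, slope = slope,
                       rate_scale = rate_scale, noise_sd = noise_sd,
                       filter_corner = filter_corner),
      activation_params = c(v_half = v_half, slope = slope, p_max = 1))
  }
  list(endothelium = mk("endothelium", 0.12, 6000),
       fibroblast  = mk("fibroblast", 0.50, 2500),
       hippocampus = mk("hippocampus", 0.88, 1000))
}

#' Similar-pair tissue profiles
#'
#' Fibroblast and hippocampus are designed kinetically similar (close
#' half-activation potentials and dwell-time scales) while endothelium is
#' distinct (right-shifted activation, fast gating). Used to check that the
#' latent-space centroid distance between the two similar classes is the
#' smallest of the three pairwise distances.
#'
#' @inheritParams default_profiles
#' @return List of three `CellProfile`s.
#' @export
similar_pair_profiles <- function(noise_sd = 0.8, filter_corner = NA_real_) {
  mk <- function(label, v_half, slope, rate_scale) {
    cell_profile(
      label,
      two_state_scheme(paste0(label, "_2state"), v_half = v_half,
                       slope = slope, rate_scale = rate_scale,
                       noise_sd = noise_sd, filter_corner = filter_corner),
      activation_params = c(v_half = v_half, slope = slope, p_max = 1))
  }
  list(endothelium = mk("endothelium", 25, 10, 6000),
       fibroblast  = mk("fibroblast", -25, 12, 2400),
       hippocampus = mk("hippocampus", -22, 12, 2000))
}

#' Perturbed scheme for planting anomalous recordings
#'
#' Builds a voltage-independent two-state scheme whose stationary open
#' probability at the given potential is shifted by `delta_pop` relative to
#' the source scheme (`type = "pop_shift"`), or adds a long-lived extra closed
#' state the channel occasionally falls into (`type = "sticky_closed"`),
#' mimicking untypical "lowered"-activity traces.
#'
#' @param scheme Source `GatingScheme` (two-state open/closed).
#' @param potential Pipette potential (mV) at which the anomaly is planted.
#' @param type `"pop_shift"` or `"sticky_closed"`.
#' @param delta_pop Open-probability shift for `"pop_shift"` (sign chosen
#'   automatically to stay inside (0, 1) when the shifted value would leave
#'   \[0.02, 0.98\]).
#' @return A `GatingScheme` with `"_anomaly"` appended to its id.
#' @export
anomaly_scheme <- function(scheme, potential, type = c("pop_shift", "sticky_closed"),
                           delta_pop = 0.3) {
  type <- match.arg(type)
  p0 <- stationary_open_probability(scheme, potential)
  Q <- rate_matrix_at(scheme, potential)
  conducting <- scheme$states$conducting
  rate_scale <- sum(-diag(Q)) / nrow(Q) * 2  # characteristic total rate
  if (type == "pop_shift") {
    p1 <- p0 + delta_pop
    if (p1 > 0.98 || p1 < 0.02) p1 <- p0 - delta_pop
    p1 <- clamp(p1, 0.02, 0.98)
    out <- two_state_scheme(paste0(scheme$scheme_id, "_anomaly"),
                            v_half = NA, p_open = p1, rate_scale = rate_scale,
                            conductance = scheme$conductance,
                            reversal_potential = scheme$reversal_potential,
                            baseline_current = scheme$baseline_current,
                            noise_sd = scheme$noise_sd,
                            filter_corner = scheme$filter_corner)
  } else {
    # C <-> O as before, plus O -> C2 (sticky) and slow C2 -> C return
    k_open <- rate_scale * p0
    k_close <- rate_scale * (1 - p0)
    states <- data.frame(name = c("C", "O", "C2"),
                         conducting = c(FALSE, TRUE, FALSE))
    trans <- data.frame(
      from = c("C", "O", "O", "C2"),
      to = c("O", "C", "C2", "C"),
      base_rate = c(k_open, k_close, 0.2 * k_close, 0.02 * rate_scale),
      v_half = NA_real_, slope = NA_real_)
    out <- gating_scheme(paste0(scheme$scheme_id, "_anomaly"), states, trans,
                         conductance = scheme$conductance,
                         reversal_potential = scheme$reversal_potential,
                         baseline_current = scheme$baseline_current,
                         noise_sd = scheme$noise_sd,
                         filter_corner = scheme$filter_corner)
  }
  out
}
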