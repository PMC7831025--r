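#' Generate a labelled synthetic dataset of recordings
#'
#' Emulates the experimental design: for every (cell profile, pipette
#' potential) pair, `n_recordings_per_class` independent recordings are
#' simulated, each a two-level current trace with the profile's gating
#' kinetics, amplitude set by the 300 pS-scale conductance, Gaussian noise and
#' optional low-pass filtering. Optionally, anomalous recordings with
#' perturbed kinetics are appended to chosen categories; they are flagged only
#' in provenance (hidden from the analysis pipeline).
#'
#' @param profiles List of `CellProfile`s (one per class).
#' @param n_recordings_per_class Replicates per (class, potential); >= 3 so
#'   leave-one-recording-per-class cross-validation is exercisable.
#' @param n_points Samples per recording.
#' @param potentials Pipette potentials (mV).
#' @param anomaly_spec Optional list with fields `cell_label`, `potential`,
#'   `count` (default 1), and either `scheme` (an explicit perturbed
#'   `GatingScheme`) or `type`/`delta_pop` passed to [anomaly_scheme()].
#'   Anomalous recordings are appended after the typical replicates of that
#'   category.
#' @param seed Integer seed; the whole dataset is deterministic per seed.
#' @param sampling_rate Sampling rate in Hz.
#' @return List with `recordings` (named list of `Recording`s) and `manifest`
#'   (data frame: recording_id, cell_label, potential_mV, sampling_rate_Hz,
#'   n_points, is_planted_anomaly).
#' @export
generate_dataset <- function(profiles, n_recordings_per_class = 3,
                             n_points = 20000,
                             potentials = c(-60, -40, -20, 20, 40, 60),
                             anomaly_spec = NULL, seed = 1,
                             sampling_rate = 4000) {
  stopifnot(n_recordings_per_class >= 3)
  recordings <- list()
  rows <- list()
  idx <- 0L
  add_rec <- function(profile, potential, replicate, scheme, planted) {
    idx <<- idx + 1L
    rid <- sprintf("%s_%+03dmV_r%d%s", profile$label, potential, replicate,
                   if (planted) "a" else "")
    if (!is.null(recordings[[rid]])) stop_cp("duplicate recording_id '%s'", rid)
    path_seed <- derive_seed(seed, 2L * idx)
    noise_seed <- derive_seed(seed, 2L * idx + 1L)
    path <- simulate_state_path(scheme, potential, n_points, sampling_rate,
                                seed = path_seed)
    rec <- render_recording(path, scheme, potential, seed = noise_seed,
                            sampling_rate = sampling_rate,
                            recording_id = rid, cell_label = profile$label)
    rec$provenance$is_planted_anomaly <- planted
    rec$provenance$true_open_fraction <-
      mean(scheme$states$conducting[as.integer(path)])
    rec$provenance$stationary_open_probability <-
      stationary_open_probability(scheme, potential)
    recordings[[rid]] <<- rec
    rows[[length(rows) + 1L]] <<- data.frame(
      recording_id = rid, cell_label = profile$label,
      potential_mV = potential, sampling_rate_Hz = sampling_rate,
      n_points = n_points, is_planted_anomaly = planted,
      stringsAsFactors = FALSE)
  }
  for (profile in profiles) {
    for (potential in potentials) {
      sch <- scheme_for(profile, potential)
      for (r in seq_len(n_recordings_per_class)) {
        add_rec(profile, potential, r, sch, planted = FALSE)
      }
    }
  }
  if (!is.null(anomaly_spec)) {
    lab <- anomaly_spec$cell_label
    pot <- anomaly_spec$potential
    count <- anomaly_spec$count %||% 1L
    profile <- NULL
    for (p in profiles) if (p$label == lab) profile <- p
    if (is.null(profile)) stop_cp("anomaly_spec names unknown class '%s'", lab)
    sch <- anomaly_spec$scheme %||%
      anomaly_scheme(scheme_for(profile, pot), pot,
                     type = anomaly_spec$type %||% "pop_shift",
                     delta_pop = anomaly_spec$delta_pop %||% 0.3)
    for (r in seq_len(count)) {
      add_rec(profile, pot, n_recordings_per_class + r, sch, planted = TRUE)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  list(recordings = recordings, manifest = manifest)
}
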