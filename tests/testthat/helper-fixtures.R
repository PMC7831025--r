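# Shared fixtures, built once per test session and memoised.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# Small well-separated dataset at one potential (9 recordings).
fix_small_dataset <- function() {
  fixture("small_ds", function() {
    generate_dataset(well_separated_profiles(), 3, n_points = 12000,
                     potentials = 40, seed = 101)
  })
}

# A single moderately long fibroblast recording (default profiles).
fix_one_recording <- function() {
  fixture("one_rec", function() {
    prof <- default_profiles()
    sch <- channelprint:::scheme_for(prof$fibroblast, 40)
    path <- simulate_state_path(sch, 40, 40000, 4000, seed = 7)
    rec <- render_recording(path, sch, 40, seed = 8, sampling_rate = 4000,
                            recording_id = "fib40", cell_label = "fibroblast")
    rec$provenance$true_open_fraction <- mean(attr(path, "conducting"))
    rec
  })
}

# Category fixture: 6 typical hippocampus recordings + 1 planted anomaly
# whose open probability is shifted from ~0.88 toward mid-range.
fix_anomaly_category <- function() {
  fixture("anomaly_cat", function() {
    ds <- generate_dataset(well_separated_profiles(), 6, n_points = 12000,
                           potentials = 40,
                           anomaly_spec = list(cell_label = "hippocampus",
                                               potential = 40, count = 1),
                           seed = 81)
    list(recordings = ds$recordings[grep("hippocampus", names(ds$recordings))],
         planted = ds$manifest$recording_id[ds$manifest$is_planted_anomaly])
  })
}

# Sine-curve manifold: a 1-D family of smooth 200-dim samples in [0, 1].
sine_manifold <- function(n = 500, d = 200) {
  grid <- seq(0, 2 * pi, length.out = d)
  t(sapply(seq(0, 2 * pi, length.out = n),
           function(ph) 0.5 + 0.4 * sin(grid + ph)))
}

# Independent dense linear-algebra oracle for the stationary distribution.
stationary_nullspace_oracle <- function(Q) {
  dec <- eigen(t(Q))
  k <- which.min(abs(dec$values))
  v <- Re(dec$vectors[, k])
  v / sum(v)
}

expect_recording <- function(rec) {
  expect_s3_class(rec, "Recording")
  expect_true(all(is.finite(rec$trace)))
  expect_gt(length(rec$trace), 0)
}
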