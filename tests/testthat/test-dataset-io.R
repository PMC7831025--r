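test_that("generate_dataset produces the full factorial design deterministically", {
  prof <- well_separated_profiles()
  ds <- generate_dataset(prof, 3, n_points = 2000,
                         potentials = c(-60, -40, -20, 20, 40, 60), seed = 9)
  expect_equal(length(ds$recordings), 54)  # 3 classes x 3 replicates x 6 potentials
  expect_equal(nrow(ds$manifest), 54)
  expect_false(any(ds$manifest$is_planted_anomaly))
  counts <- table(ds$manifest$cell_label, ds$manifest$potential_mV)
  expect_true(all(counts == 3))

  # same seed: byte-identical traces and manifest
  ds2 <- generate_dataset(prof, 3, n_points = 2000,
                          potentials = c(-60, -40, -20, 20, 40, 60), seed = 9)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(lapply(ds$recordings, `[[`, "trace"),
                   lapply(ds2$recordings, `[[`, "trace"))

  # planted anomaly: exactly one, flagged only in provenance
  ds3 <- generate_dataset(prof, 3, n_points = 2000, potentials = 40,
                          anomaly_spec = list(cell_label = "hippocampus",
                                              potential = 40, count = 1),
                          seed = 9)
  expect_equal(sum(ds3$manifest$is_planted_anomaly), 1)
  planted <- ds3$manifest$recording_id[ds3$manifest$is_planted_anomaly]
  expect_true(ds3$recordings[[planted]]$provenance$is_planted_anomaly)
})

test_that("trace files round-trip through plain and ATF dialects", {
  dir <- withr::local_tempdir()
  rec <- fix_small_dataset()$recordings[[1]]
  for (dialect in c("plain", "atf")) {
    p <- file.path(dir, paste0("t_", dialect, ".txt"))
    write_recording(rec, p, dialect = dialect)
    back <- read_recording(p, dialect = dialect)
    expect_identical(back$trace, rec$trace)
  }
  # plain headers carry metadata
  p <- file.path(dir, "meta.txt")
  write_recording(rec, p)
  back <- read_recording(p)
  expect_equal(back$recording_id, rec$recording_id)
  expect_equal(back$cell_label, rec$cell_label)
  expect_equal(back$potential, rec$potential)
  expect_equal(back$sampling_rate, rec$sampling_rate)

  # constant-zero trace round-trips exactly
  z <- new_recording("zero", "x", 0, rep(0, 100), 4000)
  pz <- file.path(dir, "zero.txt")
  write_recording(z, pz)
  expect_identical(read_recording(pz)$trace, rep(0, 100))
})

test_that("manifest validation tabulates the class-by-potential design", {
  dir <- withr::local_tempdir()
  write_dataset(fix_small_dataset(), dir)
  counts <- suppressMessages(validate_manifest(file.path(dir, "manifest.json")))
  expect_equal(dim(counts), c(3L, 1L))
  expect_true(all(counts == 3))
})

test_that("malformed trace files fail with informative errors", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.txt")
  writeLines(c("1.0", "2.0", "oops", "4.0"), bad)
  expect_error(read_recording(bad), "line 3")
  empty <- file.path(dir, "empty.txt")
  file.create(empty)
  expect_error(read_recording(empty), "empty")
  expect_error(write_recording(new_recording("x", "x", 0, 1, 4000)[c(1:6)], bad),
               class = "error")
})

test_that("an ATF file with header records parses the data block", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "h.atf")
  writeLines(c("ATF\t1.0", "2\t1", "\"Comment=synthetic\"",
               "\"AcquisitionMode=single channel\"", "\"Current (pA)\"",
               "0.5", "-1.25", "3"), p)
  rec <- read_recording(p, dialect = "atf")
  expect_equal(rec$trace, c(0.5, -1.25, 3))
})

test_that("datasets round-trip through manifest + trace files, with filtering", {
  dir <- withr::local_tempdir()
  ds <- fix_small_dataset()
  write_dataset(ds, dir)
  loaded <- load_dataset(file.path(dir, "manifest.json"))
  expect_setequal(names(loaded$recordings), names(ds$recordings))
  expect_identical(loaded$recordings[[3]]$trace, ds$recordings[[3]]$trace)
  # grouping partitions the dataset
  expect_equal(sort(unlist(loaded$groups, use.names = FALSE)),
               sort(names(loaded$recordings)))
  # potential filter
  l2 <- load_dataset(file.path(dir, "manifest.json"), potentials = 40)
  expect_equal(nrow(l2$index), 9)
  expect_equal(length(l2$groups), 3)
  # unknown label: empty result with warning, not error
  expect_warning(l3 <- load_dataset(file.path(dir, "manifest.json"),
                                    labels = "astrocyte"), "no manifest")
  expect_equal(length(l3$recordings), 0)
  # missing file is reported by recording id
  unlink(file.path(dir, paste0(names(ds$recordings)[1], ".txt")))
  expect_error(load_dataset(file.path(dir, "manifest.json")),
               names(ds$recordings)[1], fixed = TRUE)
})
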