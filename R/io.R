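#' Write a recording to a one-column text trace file
#'
#' The plain dialect writes optional `#`-prefixed header lines
#' (`recording_id`, `cell_label`, `potential_mV`, `sampling_rate_Hz`) followed
#' by one current value (pA) per line at full double precision, so traces
#' round-trip exactly through [read_recording()]. The `atf` dialect writes a
#' minimal Axon-text-format style file (version line, header-count line,
#' column-title line, then one value per line).
#'
#' @param recording A `Recording`.
#' @param path Output file path.
#' @param dialect `"plain"` or `"atf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, dialect = c("plain", "atf")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(recording, "Recording"))
  if (length(recording$trace) == 0) stop_cp("refusing to write empty trace")
  vals <- sprintf("%.17g", recording$trace)
  if (dialect == "plain") {
    hdr <- c(sprintf("# recording_id: %s", recording$recording_id),
             sprintf("# cell_label: %s", recording$cell_label),
             sprintf("# potential_mV: %g", recording$potential),
             sprintf("# sampling_rate_Hz: %g", recording$sampling_rate))
    writeLines(c(hdr, vals), path)
  } else {
    hdr <- c("ATF\t1.0",
             "1\t1",
             sprintf("\"Recording=%s; Potential=%g mV; Rate=%g Hz\"",
                     recording$recording_id, recording$potential,
                     recording$sampling_rate),
             "\"Current (pA)\"")
    writeLines(c(hdr, vals), path)
  }
  invisible(path)
}

#' Read a recording from a text trace file
#'
#' @param path File path.
#' @param dialect `"plain"` (one value per line, optional `#` headers) or
#'   `"atf"` (Axon-text-format style: `ATF` version line, a line giving the
#'   number of optional header records and columns, the header records, a
#'   column-title line, then data; only the first column is read).
#' @param cell_label,potential,sampling_rate Metadata overrides; when `NA`
#'   they are taken from the file header (plain dialect) or defaulted.
#' @return A `Recording`.
#' @export
read_recording <- function(path, dialect = c("plain", "atf"),
                           cell_label = NA_character_, potential = NA_real_,
                           sampling_rate = NA_real_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_cp("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop_cp("empty file: %s", path)
  meta <- list(recording_id = sub("\\.[^.]*$", "", basename(path)),
               cell_label = cell_label, potential = potential,
               sampling_rate = sampling_rate)
  if (dialect == "plain") {
    is_hdr <- startsWith(lines, "#")
    for (h in lines[is_hdr]) {
      m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+):\\s*(.*)$", h))[[1]]
      if (length(m) == 3) {
        key <- m[2]; val <- m[3]
        if (key == "recording_id") meta$recording_id <- val
        if (key == "cell_label" && is.na(meta$cell_label)) meta$cell_label <- val
        if (key == "potential_mV" && is.na(meta$potential))
          meta$potential <- as.numeric(val)
        if (key == "sampling_rate_Hz" && is.na(meta$sampling_rate))
          meta$sampling_rate <- as.numeric(val)
      }
    }
    data_lines <- lines[!is_hdr]
    first_data <- which(!is_hdr)
  } else {
    if (!startsWith(lines[1], "ATF")) stop_cp("not an ATF file: %s", path)
    counts <- suppressWarnings(as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]]))
    n_hdr <- if (length(counts) >= 1 && !is.na(counts[1])) counts[1] else 0L
    skip <- 2L + n_hdr + 1L  # version + counts + header records + column titles
    data_lines <- lines[-seq_len(min(skip, length(lines)))]
    first_data <- seq_along(lines)[-seq_len(min(skip, length(lines)))]
  }
  data_lines <- trimws(data_lines)
  keep <- nzchar(data_lines)
  data_lines <- data_lines[keep]
  first_data <- first_data[keep]
  if (length(data_lines) == 0) stop_cp("no data lines in %s", path)
  # first whitespace-separated column
  first_col <- sub("[\t ].*$", "", data_lines)
  vals <- suppressWarnings(as.numeric(first_col))
  if (anyNA(vals)) {
    bad <- first_data[which(is.na(vals))[1]]
    stop_cp("non-numeric value at line %d of %s", bad, path)
  }
  new_recording(meta$recording_id, meta$cell_label,
                ifelse(is.na(meta$potential), NA_real_, meta$potential),
                vals,
                ifelse(is.na(meta$sampling_rate), 4000, meta$sampling_rate))
}

#' Write a dataset (trace files + JSON manifest) to a directory
#'
#' @param dataset List with `recordings` and `manifest` as returned by
#'   [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @param dialect Trace dialect, see [write_recording()].
#' @return Path to the written `manifest.json`, invisibly.
#' @export
write_dataset <- function(dataset, dir, dialect = "plain") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(dataset$recordings, function(rec) {
    file <- paste0(rec$recording_id, ".txt")
    write_recording(rec, file.path(dir, file), dialect = dialect)
    list(recording_id = rec$recording_id, file = file,
         cell_label = rec$cell_label, potential_mV = rec$potential,
         sampling_rate_Hz = rec$sampling_rate,
         provenance = rec$provenance[c("seed", "scheme_id", "is_planted_anomaly")])
  })
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(unname(entries), manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}

#' Load a dataset from a JSON manifest
#'
#' Reads every referenced trace file and groups the recordings by
#' (cell label, potential). Filters are applied before any file is read.
#'
#' @param manifest_path Path to `manifest.json`.
#' @param labels Optional class filter.
#' @param potentials Optional potential filter (mV).
#' @return List with `recordings` (named list of `Recording`s), `index` (data
#'   frame of manifest entries kept) and `groups` (named list mapping
#'   "label@potential" to recording ids).
#' @export
load_dataset <- function(manifest_path, labels = NULL, potentials = NULL) {
  if (!file.exists(manifest_path)) stop_cp("no such manifest: %s", manifest_path)
  entries <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  root <- dirname(manifest_path)
  idx <- do.call(rbind, lapply(entries, function(e) data.frame(
    recording_id = e$recording_id, file = e$file, cell_label = e$cell_label,
    potential_mV = as.numeric(e$potential_mV),
    sampling_rate_Hz = as.numeric(e$sampling_rate_Hz),
    stringsAsFactors = FALSE)))
  if (anyDuplicated(idx$recording_id)) stop_cp("duplicate recording ids in manifest")
  if (any(!is.finite(idx$potential_mV))) stop_cp("non-finite potential in manifest")
  keep <- rep(TRUE, nrow(idx))
  if (!is.null(labels)) {
    keep <- keep & idx$cell_label %in% labels
    if (!any(idx$cell_label %in% labels))
      warning("no manifest entries match the requested labels", call. = FALSE)
  }
  if (!is.null(potentials)) keep <- keep & idx$potential_mV %in% potentials
  idx <- idx[keep, , drop = FALSE]
  prov <- lapply(entries, function(e) e$provenance %||% list())
  names(prov) <- vapply(entries, function(e) e$recording_id, character(1))
  recordings <- list()
  for (i in seq_len(nrow(idx))) {
    f <- file.path(root, idx$file[i])
    if (!file.exists(f))
      stop_cp("missing trace file for recording '%s': %s", idx$recording_id[i], f)
    rec <- read_recording(f, cell_label = idx$cell_label[i],
                          potential = idx$potential_mV[i],
                          sampling_rate = idx$sampling_rate_Hz[i])
    rec$recording_id <- idx$recording_id[i]
    p <- prov[[idx$recording_id[i]]]
    if (length(p) > 0) rec$provenance <- p
    recordings[[rec$recording_id]] <- rec
  }
  list(recordings = recordings, index = idx, groups = group_recordings(recordings))
}

#' Validate a manifest and summarize its design
#'
#' Checks the manifest invariants (unique ids, finite potentials, referenced
#' files present) and tabulates recording counts per class and potential.
#'
#' @param manifest_path Path to `manifest.json`.
#' @return A contingency table (cell label x potential) of recording counts,
#'   invisibly printed with a validity message.
#' @export
validate_manifest <- function(manifest_path) {
  ds <- load_dataset(manifest_path)
  counts <- table(ds$index$cell_label, ds$index$potential_mV,
                  dnn = c("cell_label", "potential_mV"))
  message(sprintf("manifest ok: %d recordings, %d classes, %d potentials",
                  nrow(ds$index), nrow(counts), ncol(counts)))
  print(counts)
  invisible(counts)
}

#' Group recordings by (cell label, potential)
#'
#' @param recordings Named list of `Recording`s.
#' @return Named list mapping "label@potential" to character vectors of
#'   recording ids; the groups partition the input.
#' @export
group_recordings <- function(recordings) {
  keys <- vapply(recordings, function(r)
    sprintf("%s@%g", r$cell_label, r$potential), character(1))
  ids <- vapply(recordings, function(r) r$recording_id, character(1))
  split(unname(ids), keys)
}

# Subset a named recording list to one potential.
recordings_at <- function(recordings, potential) {
  Filter(function(r) isTRUE(r$potential == potential), recordings)
}
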