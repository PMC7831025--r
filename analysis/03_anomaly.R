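#!/usr/bin/env Rscript
# Stage 3: reconstruction-error anomaly detection on the classification
# dataset, category by category (cell type x potential). Writes
# results/anomaly_report.json with per-recording scores, robust z-values and
# flags, plus the confirmation bottleneck sweep for any flagged recording.

suppressPackageStartupMessages(library(channelprint))
seed <- 11

ds <- load_dataset("scratch/data/classification/manifest.json")
report <- detect_anomalies(ds$recordings,
                           hp = train_hyperparams(epochs = 60, seed = seed))
print(report)

confirmations <- list()
for (cat in report$categories) {
  for (id in cat$flagged) {
    typical <- setdiff(names(cat$scores), cat$flagged)[1]
    cmp <- confirm_outlier(ds$recordings[[id]], ds$recordings[[typical]],
                           dims = c(1, 2, 3, 5),
                           hp = train_hyperparams(epochs = 60, seed = seed))
    message(sprintf("confirmation for %s vs %s: candidate J above typical at every dim: %s",
                    id, typical, cmp$verdict))
    confirmations[[id]] <- list(candidate = id, typical = typical,
                                candidate_curve = cmp$candidate,
                                typical_curve = cmp$typical,
                                verdict = cmp$verdict)
  }
}
out <- list(categories = lapply(report$categories, function(cat) {
  list(category = cat$category, scores = as.list(cat$scores),
       zscores = as.list(cat$zscores), flagged = cat$flagged, rule = cat$rule)
}), flagged = report$flagged, confirmations = confirmations)
jsonlite::write_json(out, "results/anomaly_report.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
message("wrote results/anomaly_report.json")
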