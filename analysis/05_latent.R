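#!/usr/bin/env Rscript
# Stage 5: 2-D latent embedding of the (anomaly-filtered) test samples per
# potential, K-means clustering (K = 3) and pairwise centroid distances.
# Assembles the final summary table (one row per potential: accuracies and
# the three class-pair distances). Latent distances are in autoencoder
# latent-space units and are not comparable across potentials.

suppressPackageStartupMessages(library(channelprint))
seed <- 31

ds <- load_dataset("scratch/data/classification/manifest.json")
flagged <- jsonlite::read_json("results/anomaly_report.json",
                               simplifyVector = TRUE)$flagged
acc <- read.csv("results/accuracy.csv")

rows <- list(); coords <- list()
for (pot in sort(unique(vapply(ds$recordings, `[[`, numeric(1), "potential")))) {
  recs <- Filter(function(r) r$potential == pot, ds$recordings)
  cleaned <- filter_dataset(recs, as.character(flagged))$recordings
  pp <- preprocess_pooled(cleaned)
  ec <- embed_and_cluster(pp$x, pp$meta$cell_label,
                          hp = train_hyperparams(epochs = 60,
                                                 seed = seed + round(pot)),
                          seed = seed + round(pot) + 1L)
  message(sprintf("%+4d mV: cluster/label agreement %.2f; distances %s",
                  pot, ec$agreement,
                  paste(sprintf("%s=%.3f", names(ec$distances), ec$distances),
                        collapse = ", ")))
  rows[[as.character(pot)]] <- data.frame(
    potential_mV = pot, t(ec$distances), agreement = ec$agreement,
    check.names = FALSE)
  coords[[as.character(pot)]] <- data.frame(
    potential_mV = pot, x = ec$embedding[, 1], y = ec$embedding[, 2],
    cell_label = pp$meta$cell_label, recording_id = pp$meta$recording_id,
    offset = pp$meta$offset)
}
dist_tab <- do.call(rbind, rows)
write.csv(do.call(rbind, coords), "scratch/latent_coordinates.csv",
          row.names = FALSE)

summary_tab <- merge(acc[, c("potential_mV", "acc_without_ad", "acc_with_ad")],
                     dist_tab, by = "potential_mV")
summary_tab <- summary_tab[order(summary_tab$potential_mV), ]
write.csv(summary_tab, "results/summary_table.csv", row.names = FALSE)
message("summary table (latent distances not comparable across potentials):")
print(summary_tab, row.names = FALSE, digits = 4)
message("wrote results/summary_table.csv (scatter data in scratch/latent_coordinates.csv)")
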