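#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic study datasets.
#
# Two datasets are written under scratch/data/:
#   activation/     three voltage-activated tissue profiles (voltage-activated
#                   kinetics, ms-scale dwells) for the kinetic analysis;
#   classification/ three well-separated profiles (flicker-range dwells,
#                   occupancies ~0.12/0.5/0.88) with one planted anomalous
#                   recording, for anomaly detection + classification.

suppressPackageStartupMessages(library(channelprint))
seed <- 1
potentials <- c(-60, -40, -20, 20, 40, 60)
n_points <- 20000

message("simulating activation dataset (default tissue profiles) ...")
ds_act <- generate_dataset(default_profiles(), 3, n_points = n_points,
                           potentials = potentials, seed = seed)
write_dataset(ds_act, "scratch/data/activation")
message("  ", length(ds_act$recordings), " recordings written")

message("simulating classification dataset (well-separated profiles) ...")
ds_cls <- generate_dataset(well_separated_profiles(), 4, n_points = n_points,
                           potentials = potentials,
                           anomaly_spec = list(cell_label = "hippocampus",
                                               potential = 40, count = 1),
                           seed = seed + 1)
write_dataset(ds_cls, "scratch/data/classification")
planted <- ds_cls$manifest$recording_id[ds_cls$manifest$is_planted_anomaly]
message("  ", length(ds_cls$recordings), " recordings written (planted anomaly: ",
        planted, ")")
message("done; manifests under scratch/data/*/manifest.json")
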