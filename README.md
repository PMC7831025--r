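# channelprint

Recognizing the cell type of origin of a mitochondrial BK (mitoBK) channel
from short excerpts of single-channel patch-clamp current recordings.

mitoBK channels from different tissues are co-assembled with different
auxiliary β subunits, and their gating dynamics — the stochastic switching
between conducting and non-conducting conformations visible in a
patch-clamp current trace — carry a tissue-specific "fingerprint" even when
summary statistics such as the open probability are similar. `channelprint`
implements, as a tested R package plus a numbered analysis workflow, the
full machine-learning pipeline for extracting and validating that
fingerprint, together with the classical kinetic analysis
(threshold current, open probability, voltage-activation curve) and a
Markov-gating simulator that generates labelled synthetic recordings so
every stage is testable without access to experimental data.

The intended users are electrophysiologists and computational biologists who
want a reproducible, scriptable version of this analysis for their own
single-channel recordings (plain-text traces plus a JSON manifest) or for
simulation studies of its behavior.

## The pipeline

For recordings grouped by cell type and pipette potential
U<sub>m</sub> ∈ {−60, −40, −20, +20, +40, +60} mV:

1. **Anomaly detection.** Per (cell type, potential) category, all
   recordings are windowed and a symmetric feed-forward autoencoder
   (200–100–50–2–50–100–200, sigmoid activations) is trained to reproduce
   its input by minimizing the mean reconstruction error
   J = (1/N) Σᵢ ‖x′ᵢ − xᵢ‖². Recordings whose mean per-window J stands out
   (one-sided robust z-score > 3.5) are flagged and removed; a
   J-versus-bottleneck-dimension sweep confirms each flag.
2. **Preprocessing.** Recordings are truncated to the shortest common
   length, split into windows of l = 1000 points with stride r = 200
   (floor((L−l)/r) windows per recording), compressed to w = 200 points by
   piecewise aggregate approximation (equal-frame means), and min-max
   scaled to [0, 1] (scaling fitted on each fold's training windows).
3. **Classification.** Leave-one-recording-per-class cross-validation over
   the full Cartesian product of test choices; K-nearest neighbors (K = 5,
   Euclidean metric) on the 200-dimensional windows; per-fold confusion
   matrices summed, accuracy = 100 · diagonal/total.
4. **Latent separation.** Per potential, samples are compressed to a 2-D
   autoencoder latent space (visualization only — never used for
   classification); K-means (K = 3, Lloyd iterations, best of 10 random
   restarts) locates class centroids and the three pairwise centroid
   distances quantify class separation.

Kinetic analysis: the threshold current TC separating conducting from
non-conducting samples is the intersection of two power-law fits flanking
the inter-modal valley of the Epanechnikov-kernel density of log
amplitudes; p_op is the fraction of samples beyond TC; p_op(U_m) is fitted
by the Boltzmann sigmoid p_max / (1 + exp(−(U_m − V₁/₂)/s)).

The synthetic-data generator simulates two-state (and arbitrary-state)
continuous-time Markov gating by exact event sampling, with per-transition
Boltzmann voltage dependence, 300 pS-scale conductance, Gaussian noise,
optional 1 kHz single-pole low-pass filtering, 4 kHz sampling, and
optionally plants anomalous recordings (shifted open probability or a
sticky extra closed state) that are flagged only in provenance.

## Worked example

```r
library(channelprint)

# three synthetic classes, 3 recordings each, at +40 mV
ds <- generate_dataset(well_separated_profiles(), 3, n_points = 12000,
                       potentials = 40, seed = 7)

rec <- ds$recordings[["fibroblast_+40mV_r1"]]
rec
#> <Recording fibroblast_+40mV_r1> fibroblast at +40 mV, 12000 points @ 4000 Hz

th <- estimate_threshold_current(rec)
th
#> <ThresholdEstimate> TC = 5.363 pA (power_law; bw = 0.242, grid 512)
open_probability(rec, th$tc)
#> [1] 0.5000833   # designed open probability: 0.5

run_cross_validation(ds$recordings)
#> <CVResult> 27 folds, overall accuracy 100.00% (fold mean 100.00%)
#>              predicted
#> true          endothelium fibroblast hippocampus
#>   endothelium        1485          0           0
#>   fibroblast            0       1485           0
#>   hippocampus           0          0        1485
```

The threshold current (5.4 pA) falls between the closed level (~0 pA) and
the open level (300 pS × 40 mV = 12 pA); the recovered open probability
matches the designed value; and the 27-fold cross-validated KNN assigns
every one of the 3 × 27 × 55 test windows to the correct cell type.

## The analysis workflow

The numbered scripts under `analysis/` run the full study on synthetic
data and write tables under `results/` (bulky intermediates such as the
simulated traces go to `scratch/`):

```sh
Rscript analysis/01_simulate.R    # two datasets -> scratch/data/
Rscript analysis/02_kinetics.R   # TC, p_op, activation fits -> results/
Rscript analysis/03_anomaly.R    # per-category anomaly report -> results/
Rscript analysis/04_classify.R   # CV accuracy with/without filtering
Rscript analysis/05_latent.R     # centroid distances + summary table
```

On the shipped configuration the planted anomalous recording is the only
flag, classification at +40 mV improves from 93.8% to 100% once it is
removed, a label-permutation control sits at ~35% (chance = 33.3%), and
the summary table (`results/summary_table.csv`) lists per-potential
accuracies and the three class-pair latent distances.

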