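---
title: "Methods: recognizing cell types from single-channel gating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recognizing cell types from single-channel gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`channelprint` classifies the cell type of origin of a mitochondrial BK
channel from short excerpts of single-channel current recordings, and
quantifies how separable the tissue-specific gating patterns are. This
vignette documents the models, the tunable parameters, the numerical
choices, and the limits of what the synthetic validation shows.

## The gating simulator

Single-channel gating is modelled as a continuous-time Markov chain over a
small set of conformational states, each tagged conducting or
non-conducting. The generator matrix is resolved at the pipette potential
`U`: a transition with parameters (base rate, `v_half`, `slope`) has rate
`base_rate / (1 + exp(-(U - v_half)/slope))`, a Boltzmann factor that rises
(positive slope) or falls (negative slope) with depolarization; transitions
without `v_half` are voltage-independent. Simulation is by exact event
sampling — exponential holding times from the current state's total exit
rate, embedded-chain jumps — followed by zero-order-hold resampling at the
sampling rate, so dwell-time statistics are exact regardless of the
sampling interval. The observation model adds the open-channel current
`conductance * (U - reversal) / 1000` pA (300 pS and 0 mV reversal by
default, i.e. 18 pA at +60 mV and −18 pA at −60 mV), a baseline offset,
Gaussian noise (default SD 0.8 pA), and optionally a causal single-pole
low-pass filter (the simplest filter with a defined corner; default off for
analysis transparency, 1 kHz for realism runs). Sampling is 4 kHz by
default and configurable.

The canonical two-state scheme parameterizes opening as
`rate_scale * p_max * sigma(U)` and closing as
`rate_scale * (1 - p_max * sigma(U))`, which makes the stationary open
probability exactly `p_max * sigma(U)` while `1 / rate_scale` sets the
dwell-time scale — activation curve and gating speed are independent dials.

Three profile families ship with the package:

* `default_profiles()` — the realistic family: half-activation potentials
  +5 / −20 / −30 mV, slopes 12 / 14 / 10 mV, rate scales 500 / 200 / 100
  s⁻¹ (mean dwells roughly 1–10 ms), shared 300 pS conductance. Open
  probabilities converge at strongly polarized potentials while the
  dwell-time structure stays distinct. `p_max = 0.95` for all three: a
  fully saturating curve (`p_max = 1`) leaves a 10–50 s trace at +60 mV
  with no closures at all, which makes the two-level threshold analysis
  undefined; real patches keep brief closures at saturating voltage.
* `well_separated_profiles()` — the strongly discriminable fixture:
  near-voltage-flat open probabilities ~0.12 / 0.50 / 0.88 with rate
  scales 6000 / 2500 / 1000 s⁻¹ (mean dwells ~0.2–3 ms, the flicker
  range). The fast gating is deliberate: each 5-point frame of the
  piecewise aggregate approximation then averages over several gating
  events, so window vectors concentrate near the class occupancy level and
  the classes separate in Euclidean distance. With slow (many-ms) dwells
  and equal amplitudes, two classes with occupancies 0.5 and 0.9 are
  nearly equidistant in raw Euclidean terms — windows differ wherever
  dwell patterns happen to disagree — and nearest-neighbor classification
  degrades; this fixture is designed to isolate the pipeline mechanics
  from that harder regime.
* `similar_pair_profiles()` — fibroblast and hippocampus nearly identical
  (half-activation −25 vs −22 mV, rate scales 2400 vs 2000 s⁻¹),
  endothelium distinct (+25 mV, 6000 s⁻¹); used to check that latent-space
  centroid distances rank the designed similarity correctly.

Planted anomalies substitute, for chosen recordings, either a scheme whose
stationary open probability is shifted by ±0.3 (sign flipped automatically
to stay inside [0.02, 0.98]) or a three-state scheme with a long-lived
extra closed state. Anomalous recordings are appended after the typical
replicates and flagged only in provenance, invisible to the pipeline. What
the generator does **not** emulate: sub-conductance states, stacked
multi-channel openings, baseline drift, seal breakdown, 1/f or correlated
instrument noise, and Ca²⁺-dependence; passing tests on synthetic data
therefore show that the pipeline recovers what the model family can
express, not that it is robust to every artifact of real patches.

## Kinetic analysis

The threshold current TC separating conducting from non-conducting samples
is estimated from the kernel density of absolute amplitudes (Epanechnikov
kernel, 512-point grid, Silverman bandwidth on log amplitudes; a small
offset of half a linear grid step guards log(0)). On each side of the
valley between the two amplitude modes, the widest contiguous stretch on
which log-density is linear in log-amplitude (rolling least-squares fit
with R² ≥ 0.98, minimum 5 grid points) is taken as the power-law flank; TC
is the abscissa where the two fitted lines intersect. The source procedure
is visual and quantitatively underspecified, so these three knobs
(bandwidth, grid, R² threshold) are explicit parameters rather than hidden
constants. Two numerical guards matter: the compactly supported kernel
produces exact zeros in the inter-modal gap, whose flat log-floor would
otherwise masquerade as a perfect power law, so flanks are fitted only
where the density is genuinely positive; and the left flank must decay
while the right flank rises, otherwise the estimate falls back to the
geometric midpoint of the two modes (`method = "midpoint"`, recorded, not
silent — on the shipped profiles the fallback engages in roughly a third
of the recordings, typically at extreme open probabilities where one mode
is thin). Working on |trace| makes one rule cover both signs of potential.

`open_probability` is a per-sample census (fraction of |current| above
TC), hence invariant to sign flips and sample order. The activation curve
`p_op(U) = p_max / (1 + exp(-(U - v_half)/slope))` is fitted by
Levenberg–Marquardt with bounds (p_max ≤ 1, slope > 0, rising curve
assumed); constant p_op across potentials is rejected as degenerate rather
than fitted (slope unidentifiable).

## Preprocessing and cross-validation

Windows of l = 1000 points, stride r = 200, reduced to w = 200 points by
equal-frame means. Exactly `floor((L - l)/r)` windows are emitted per
recording — the printed count formula, although enumerating offsets
0, r, … up to L − l would admit one more; the formula wins and the
discrepancy is documented here. Truncating all recordings to the shortest
length first means every recording contributes the same number of windows
(no class imbalance). Offsets are 0-based half-open internally.

Cross-validation enumerates the full Cartesian product of
one-test-recording-per-class choices, ordered lexicographically by
recording id. Min-max scaling to [0, 1] is fitted on the fold's training
windows only and applied unchanged (with clipping, counted) to the test
windows — the source is ambiguous about scaling scope, and fitting on all
data would leak test information; `normalization_scope = "joint"`
reproduces the naive all-data reading for comparison. Windows never span
recording boundaries and inherit their recording's label.

## Autoencoder

Symmetric feed-forward network 200–100–50–b–50–100–200 (bottleneck b = 2
by default), sigmoid on every layer (a linear output is available since
inputs are scaled to [0, 1]; the default keeps sigmoid throughout, matching
the stated activation). Training minimizes
J = (1/N) Σ ‖x′ᵢ − xᵢ‖² by minibatch Adam — learning rate 1e-3, batch 64,
200 epochs, Glorot-uniform initialization — robust defaults for small
sigmoid MLPs; none of these are stated by the source, so all are exposed
in `train_hyperparams()`. All randomness (initialization and batch order)
derives from the hyperparameter seed, and the returned model carries the
parameters of the epoch with the lowest full-data J, so the logged final
error never exceeds the initial one. Gradients are verified against finite
differences in the test suite. Analysis runs in this repository use 50–120
epochs on windows from 12 000–20 000-point recordings, which suffices for
the reconstruction-error contrasts the pipeline needs.

## Anomaly detection

Per (cell type, potential) category, one bottleneck-2 autoencoder is
trained on **all** windows of the category, suspects included; each
recording's score is the mean J over its own windows. Flagging replaces
the source's visual call with a rule: one-sided modified z-score
`(score - median) / (1.4826 * MAD) > 3.5`. Two robustness choices:

* The scale is floored at 5% of the median score. With 6–10 recordings per
  category the MAD can collapse on benignly tight scores, turning a
  percent-level fluctuation into a huge z-value, while genuine anomalies
  deviate by large fractions of the typical score (in the shipped studies,
  planted anomalies score z ≳ 13 against benign maxima well below the
  threshold once the floor is active). An IQR rule covers the MAD = 0
  corner.
* Flagging is one-sided: only anomalously **large** reconstruction errors
  flag, matching the statistic's meaning.

A flagged recording can be confirmed by the bottleneck sweep: J as a
function of bottleneck dimension for the suspect versus a typical
recording, the suspect's curve lying above at every dimension.

A genuine limitation, documented rather than hidden: the mean-J score is
sensitive to deviations that **increase** signal variance or complexity.
A shift of open probability from an extreme (e.g. 0.88) toward mid-range —
the analogue of a high-activity channel showing "lowered" activity —
raises per-window variance and is detected reliably; the reverse shift
(mid-range toward an extreme) **reduces** window variance, reconstructs
more easily than the typical data, and can evade the statistic entirely
(it produces the *minimum* score in our experiments). The shipped anomaly
studies therefore plant extreme-to-mid shifts; per-category score
distributions, not only flags, are reported so the other direction remains
auditable.

Anomaly detection runs before splitting, scaling and classification, and
the anomaly autoencoder is trained with the suspect included, matching the
train-on-everything-then-spot-the-standout workflow. Filtering refuses to
leave any class below two recordings (cross-validation would be
impossible).

## Classification and latent separation

KNN with K = 5 and the Euclidean metric on the 200-dimensional windows —
never on the latent embedding, which is reserved for visualization and
separation measurement (a wiring test asserts this). Tie-breaking is
deterministic where the source is silent: equal distances at the K-th rank
resolve by training order (stable sort); tied majority votes resolve to
the class with the smaller summed neighbor distance, then lexicographic
class order. Accuracy is the diagonal fraction of the summed overall
confusion matrix (the binary formula generalized to three classes); the
unweighted per-fold mean is reported alongside, since the source describes
both a summed matrix and a per-round average.

K-means uses Lloyd iterations from K distinct data points chosen at
random, 10 restarts, best inertia kept; empty clusters are re-seeded with
the worst-fit point; the inertia trajectory is logged (non-increasing by
construction) and the implementation is tested against both a
nearest-centroid oracle and `stats::kmeans`. Clusters map to classes by
majority, with collisions resolved by the exhaustive maximum-agreement
permutation (K = 3: six candidates). Centroid distances are reported per
class pair in latent-space units; because each potential gets an
independently trained autoencoder, distances are **not comparable across
potentials**. "Average distance" is ambiguous in the source
(per-fold average vs one pooled embedding); both are implemented
(`distance_mode = "per_fold"` averages the per-fold test-set distances,
`"single_shot"` embeds all pooled windows once) and the analysis scripts
use `single_shot` for speed, stating so.

## Problem sizes and determinism

The validation studies use synthetic recordings of 12 000–20 000 samples
(1 000–4 000 samples in micro-tests), 3–6 recordings per class, all six
potentials for end-to-end runs, and n = 2×10⁵ samples where stationary
occupancy and dwell statistics are checked against theory; these sizes are
the package's chosen balance between statistical resolution and quick
iteration, and every number reported by the scripts is recomputed at run
time. Determinism is end-to-end: dataset generation, training, restarts
and shuffles all derive from explicit integer seeds (`derive_seed` keeps
derived seeds inside 32-bit range), and identical seeds reproduce results
bit-for-bit.

## Known limitations

* The autoencoder is a plain sigmoid MLP; no convolutional, recurrent or
  variational variants, no GPU path.
* Anomaly detection is per-recording, not per-window or streaming, and has
  the variance-direction blind spot described above.
* The threshold-current estimator assumes a bimodal amplitude density; it
  refuses unimodal traces ("cannot separate states") rather than guessing,
  and single-channel occupancy only (no stacked openings correction).
* Latent distances depend on the trained embedding; they rank separation
  within a potential but carry no physical units.
* The simulator's noise is white and Gaussian; filtering is single-pole.
  Real recordings with colored noise, drift or seal artifacts may need
  upstream cleaning that this package does not provide.
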