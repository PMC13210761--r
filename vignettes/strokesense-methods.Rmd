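---
title: "Methods: bilateral-IMU stroke analysis and expertise classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bilateral-IMU stroke analysis and expertise classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, the signal-processing choices, and the
design decisions behind `strokesense`, in the spirit of a statistical
methods section: what is computed, under which assumptions, with which
defaults, and what the synthetic validation does and does not demonstrate.

## The measurement model

A stroke is observed through two wrist-worn 6-axis inertial sensors sampled
at 60 Hz. The dominant (racquet) wrist carries the impact signature; the
non-dominant wrist acts as a stabilizer whose coupling to the racquet arm
reflects the quality of the kinetic chain. All acceleration is handled in
units of g (conversion from the raw logger unit divides by 9.81 m/s² per g);
angular velocity stays in deg/s. The canonical container is a T×12 matrix:
columns 1–6 dominant AccX..GyrZ, 7–12 the non-dominant wrist in the same
order (channel names F1..F12).

Synchronization uses nearest-timestamp alignment with no interpolation.
Both streams share the same nominal rate, so resampling would only inject
interpolation error; residuals beyond half a sample period (≈8.3 ms) are
treated as a hard synchronization failure rather than silently tolerated.

## Impact detection and windowing

Detection operates on the Euclidean magnitude of the dominant-wrist
acceleration after zero-phase low-pass filtering (2nd-order Butterworth,
10 Hz cutoff, applied forward–backward via `signal::filtfilt`). The
zero-phase property matters: a causal filter would delay the peak and bias
the window placement. Upper-limb stroke content sits below ~20 Hz, and the
10 Hz cutoff suppresses sensor noise while preserving impact timing.

* **Dynamic threshold.** Peaks are strict local maxima at or above 20 g.
  If fewer than 4 peaks are found (the warm-up exclusion plus one), the
  detector re-runs once at 12 g and keeps the run with more peaks. The
  trigger count is our reification of "a stroke could not be detected":
  with fewer than `skip_first + 1` detections no analyzable stroke would
  survive.
* **Refractory span.** 100 samples (one full window), keeping the largest
  peak within any conflict. This guarantees non-overlapping windows.
* **Warm-up exclusion.** The first three detected strokes per recording
  are familiarization strokes and are dropped before windowing.
* **Windowing.** 40 samples before the peak, the peak, 59 after
  (40 + 1 + 59 = 100 samples ≈ 1.66 s at 60 Hz), covering preparation,
  impact, and follow-through. Windows are cut from the low-passed
  12-channel data with the same zero-phase filter used for detection.
  Whether thresholding applies to filtered or raw magnitude is a genuinely
  open choice; we filter first so that both detection and the model see the
  same noise floor.
* **Re-centering and rejection.** If filtering moves the in-window argmax
  off centre by ≤2 samples the window is re-cut at the shifted peak;
  larger shifts reject the window. Boundary windows are rejected rather
  than padded — padding would fabricate the pre-impact phase that the
  classifier relies on. Every accepted window therefore has its
  dominant-magnitude argmax exactly at row 41.

## The handcrafted feature bank

Per channel (16 features × 12 channels) plus 3 bilateral features × 6
channel pairs = **210 features**. This count is a consequence of our
scalarization choices, not an external constant. Decisions worth recording:

* **Zero crossings** count strict sign changes; exact zeros inherit the
  previous sign (no hysteresis threshold).
* **Kurtosis** is the Pearson moment ratio m₄/m₂² (3 for a Gaussian), and a
  constant signal reports 0 with a degeneracy flag rather than NaN.
* **Spectral estimates** use the unwindowed periodogram with the DC bin
  excluded; the median frequency interpolates linearly between bins.
* **Wavelet band energies** come from a periodized db4 decomposition at
  level 3, implemented directly from the orthonormal Daubechies filter
  pair. Odd-length intermediate signals are zero-padded by one sample
  before each periodized step; this keeps the transform orthogonal, so the
  four band energies sum to the signal energy to machine precision — a
  property the test suite checks at 1e-9 relative tolerance.
* **Teager–Kaiser energy** Ψ[n] = x²[n] − x[n−1]x[n+1] is summarized per
  window by its mean and max (the operator itself is a sequence; a scalar
  summary is required for a feature vector).
* **Bilateral energy ratio** is dominant over non-dominant
  (Σd²/(Σnd²+1e-8)); the direction is a convention fixed here.
* **Z-scoring** is fitted strictly on training rows; columns with zero
  training SD are centred but not divided.
* **MRMR** uses the MID (mutual-information difference) scheme on 10-bin
  equal-frequency discretizations, with ties broken to the lowest column
  index so selection is fully deterministic.

## Biomarkers and statistics

The **Asymmetry Index** is
AsIn = |m_dom − m_nd| / (m_dom + m_nd + ε), ε = 1e-8,
where m is the *window mean of per-sample Euclidean acceleration norms* —
not the norm of the mean, which would cancel oscillation. AsIn lies in
[0, 1), is invariant to common rescaling of both wrists, and symmetric
under hand swap. Lower values indicate tighter bilateral coordination.

Peak statistics use acceleration channels only. The two-way ANOVA
(stroke × expertise) uses **Type-II sums of squares** because the design is
unbalanced (more amateurs than elites); partial η² is
SS_effect/(SS_effect+SS_residual), and the package always recomputes it
from its own SS entries rather than trusting any externally printed value.
Cohen's d uses the (n−1)-weighted pooled SD.

## The classifier

Input is the N×100×12×1 window tensor. The default `cnn_bilstm` variant:

1. temporal convolution, kernel (5×1), 32 filters, shared across channels —
   learns intra-channel dynamics;
2. batch norm, ReLU, (2×1) max-pool — halves the time axis to 50;
3. **spatial fusion**: a (1×12) convolution spanning every channel (and
   every temporal filter) at each time step, 64 filters — collapses the
   bilateral channel axis to one, letting the network correlate the two
   wrists directly;
4. a bidirectional LSTM, 128 units per direction, reading the 50-step
   sequence forward and backward; the concatenated final hidden states
   (256-dim) are the learned embedding;
5. dropout 0.5, dense softmax over the two classes.

Ablations drop the recurrent block (`cnn_only`, global average pooling) or
the convolutional front end (`bilstm_only`, `gru_only` on the raw
100×12 sequence). Filter counts, the pooling span and the readout
(final-state concatenation rather than sequence pooling) are our choices,
sized for single-CPU training; the kernel shapes, unit count, dropout rate
and all optimizer hyper-parameters (Adam, lr 1e-3, step decay γ=0.2 every
15 epochs, weight decay 5e-3, batch 64, cross-entropy, 50 epochs max) are
the package defaults. Weight decay is applied through the decoupled
(AdamW-style) mechanism, which is not identical to L2 regularization inside
Adam's moment estimates — a deliberate, documented equivalence caveat.

The network and its backpropagation are implemented in vectorised base R
against BLAS matrix products; analytic gradients for every variant are
verified against central finite differences in the test suite. Inputs are
standardized per channel with statistics fitted on the training data only
(stored in the model, reapplied at prediction), which puts accelerometer
(±40 g) and gyroscope (±1500 deg/s) channels on a common scale without
leaking held-out information.

**Augmentation** (random time shift ≤5 samples with edge replication,
Gaussian jitter at 2% of per-channel RMS, amplitude scaling in [0.9, 1.1],
one copy per window) is applied exclusively to training folds; evaluation
always sees unaltered windows, and the test suite asserts bit-identity.

## Evaluation

Stratified 5-fold CV at the stroke level is the default, mirroring the
within-recording evaluation design this pipeline models; `subject_level`
folds (no participant spans folds) are provided as the stricter
alternative, because stroke-level partitioning lets a model exploit
participant idiosyncrasies and can inflate accuracy. All data-dependent
fitting — scaling, selection, augmentation, training — happens per fold on
the training partition.

The **Polygon Area Metric** places six metrics (CA, SE, SP, AUC, JI, FM —
elite is the positive class) on the spokes of a regular hexagon and
reports polygon area normalized by the maximal area 3√3/2. The formula is
reconstructed from the metric's standard definition (normalized radar
area); with all metrics equal to r the score is r², a scaling law the
tests check on a grid, and the fixed adjacency order is part of the
definition since the area is order-dependent.

Classical baselines run on the MRMR-selected features: RBF-SVM, naive
Bayes (`e1071`), random forest (`randomForest`), LDA (`MASS`), and — since
no installed package provides them — hand-rolled bagged trees, AdaBoost.M1
over depth-1 `rpart` stumps, and (weighted) kNN on a Euclidean distance
matrix. AUC uses each model's probability or decision score.

## The synthetic-data generator

The simulator defines the study conditions the package is validated under:
39 participants (11 elite, 28 amateur), each contributing 20 forehands,
20 backhands, 10 serves and 10 volleys after 3 warm-up strokes per
recording — 2340 protocol strokes.

Each archetype template is a damped-sinusoid construction over the
100-sample canonical window: a low-frequency preparatory swing, a
symmetric impact bump at row 41, and post-impact ringing whose frequency
and decay differentiate the strokes (serve: highest-frequency multi-axial
content; volley: high-damping impulse with minimal swing; backhand: most
bilaterally symmetric). Gyroscope channels are scaled, 3-sample-delayed
copies of the acceleration waveforms (25 deg/s per g) — no independent
gyro morphology is claimed. Default template peaks are 30–38 g, safely
above the 20 g detection threshold.

Class structure: elite strokes scale the dominant peak by
`elite_peak_gain` (default 1.125, the middle of a 10–15% advantage) with
smaller relative variance (SD 0.05 vs 0.10, both clamped to ±20–50% so
every stroke stays detectable); amateurs receive added 3–8 Hz pre-impact
fluctuation at 20% of peak over samples 1–36. The non-dominant amplitude
is set per stroke to hit a drawn asymmetry target (elite median 0.22,
amateur 0.32, with per-stroke-type multipliers — backhand 0.35 of the
median, reflecting its two-handed symmetry) before measurement noise
(default 0.5 g) is added. A per-type elite gain override exists to emulate
inversions such as amateurs out-accelerating elites on volleys, but the
default keeps a uniform gain. The inter-stroke gap is 180 samples (3 s),
so windows can never overlap.

**What passing tests show — and do not show.** The simulator reproduces
the *relational* structure of expert/amateur stroke data (orderings,
ratios, asymmetry gaps), not absolute field values, sensor saturation,
drift, gravity orientation, or inter-participant biomechanical diversity.
Near-perfect synthetic CV accuracy therefore validates the pipeline's
mechanics (alignment, leakage hygiene, optimization, metric computation),
not field performance on real athletes.

## Numerical choices and degenerate inputs

* Constant/zero signals yield flagged zeros (kurtosis, Hjorth, spectral,
  correlation) rather than NaN; ε-stabilized ratios (AsIn, energy ratio)
  use 1e-8.
* Peak ties in detection keep the larger magnitude, then the earlier
  index; MRMR and MI ranking break ties to the lowest column index;
  class-prediction ties take the first class.
* Batch normalization uses ε = 1e-5 and momentum 0.1 for running
  statistics; batches of one row are skipped.
* Forget-gate biases initialize at +1; convolutions use He-scaled normal
  initialization, recurrent weights uniform ±1/√U.
* All stochastic stages (simulation, folds, initialization, shuffling,
  dropout, augmentation) are driven by explicit integer seeds; stage seeds
  derive from a global seed with fixed offsets so each stage is
  independently reproducible.

## Problem sizes used in validation

The shipped tests and the acceptance script validate at desk scale, chosen
so the whole battery runs on one CPU: classifier cross-validation uses
~800 windows with a reduced architecture (4 temporal / 8 spatial filters,
16 BiLSTM units, batch 128, 25 epochs) — the separability of the synthetic
classes makes larger capacity unnecessary, and the package defaults retain
the full-size architecture. Biomarker statistics run on the full simulated
2340-stroke protocol. Statistical properties (chance-level behaviour,
effect-size recovery) use 300–1000 replicates or ≥500 strokes per class.

## Known limitations

* The recurrent variants trained on raw 100-step sequences converge slowly
  on subtle amplitude differences at small learning rates; the ablation
  comparison in the tests is a single-split, desk-scale check, not a full
  multi-seed benchmark.
* Stroke-level CV remains the default despite its optimistic bias under
  participant idiosyncrasy; use `mode = "subject_level"` for unbiased
  generalization estimates.
* t-SNE projection of embeddings is intentionally out of scope; `embed()`
  exports the penultimate representations for external projection.
* The simulator draws each stroke independently; it does not model fatigue
  trends, autocorrelation across a recording, or sensor saturation.
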