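# strokesense

Classify tennis-player expertise (elite vs amateur) from synchronized
**bilateral wrist IMU recordings** — one 6-axis inertial sensor (tri-axial
accelerometer + gyroscope, 60 Hz) on each wrist — at the level of the
individual stroke.

Skilled strokes differ from amateur ones in peak acceleration, pre-impact
smoothness, and above all in *bilateral coordination*: the stabilizing
non-dominant arm of an expert tracks the racquet arm far more consistently.
`strokesense` implements an end-to-end pipeline that turns raw per-wrist
sensor logs into these digital biomarkers and a cross-validated expertise
classifier:

1. **Signal I/O** — read per-wrist CSV logs, convert m/s² → g, pair
   `sens1`/`sens2` files by participant with a regexp, and align the two
   streams by nearest timestamp into a T×12 bilateral recording.
2. **Segmentation** — detect impacts on the zero-phase low-passed (2nd-order
   Butterworth, 10 Hz) dominant-wrist magnitude
   `Mag[n] = √(Accx² + Accy² + Accz²)` with a dynamic threshold (20 g,
   falling back to 12 g), drop the first three strokes of every recording
   (warm-up), and cut 100-sample windows — 40 samples before the peak, the
   peak, 59 after — stacked into an `N × 100 × 12 × 1` tensor.
3. **Features** — per channel: MAV, RMS, waveform length, zero crossings,
   kurtosis; mean/median frequency; periodized db4 level-3 wavelet band
   energies (E_a3, E_d1..d3); Hjorth activity/mobility/complexity; and the
   Teager–Kaiser energy operator `Ψ[n] = x²[n] − x[n−1]·x[n+1]`.
   Per bilateral channel pair: correlation, energy ratio, covariance.
   210 features total, with fold-internal z-scoring and greedy MRMR
   selection of the top 50.
4. **Biomarkers** — the bilateral Asymmetry Index
   `AsIn = |m_dom − m_nd| / (m_dom + m_nd + ε)` (window means of the
   per-sample acceleration magnitude, ε = 1e-8), per-group peak statistics,
   Type-II two-way ANOVA (stroke × expertise) with partial η², and Cohen's d.
5. **Model** — a CNN-BiLSTM with a *spatial-fusion* layer: (5×1) temporal
   convolutions per channel → batch norm/ReLU/(2×1) max-pool → a (1×12)
   convolution fusing all bilateral channels at each time step → a 128-unit
   bidirectional LSTM → dropout 0.5 → softmax. Trained with Adam (lr 1e-3,
   step decay ×0.2 every 15 epochs, decoupled weight decay 5e-3), with
   time-shift/jitter/scale augmentation applied **only** to training folds.
   Ablation variants: 1D-CNN, BiLSTM, GRU. The full network, including
   backpropagation, is implemented in vectorised base R.
6. **Evaluation** — stratified (or subject-level) 5-fold CV, per-stroke
   confusion matrices, precision/recall/F1, ROC-AUC, Jaccard index, the
   **Polygon Area Metric** (normalized hexagon area over CA, SE, SP, AUC,
   JI, FM), eight classical baselines (RBF-SVM, bagged trees, random
   forest, kNN, weighted kNN, naive Bayes, AdaBoost, LDA), and
   mutual-information feature ranking.

Because real athlete recordings are typically private, the package ships a
seeded **synthetic stroke simulator** that emits the same CSV dialect with
ground truth: four stroke archetypes (forehand/backhand/serve/volley) with
distinct impact/ringing morphology, elite peaks ~12.5% higher with lower
variance, amateur pre-impact fluctuation, and class-specific asymmetry
targets. Every stage of the pipeline is testable against it.

## Worked example

```r
library(strokesense)

# 1. simulate a small bilateral dataset: 2 elite + 3 amateur participants
cfg <- simulation_config(n_elite = 2, n_amateur = 3, seed = 42)
dir <- file.path(tempdir(), "demo")
sim <- simulate_dataset(cfg, dir, overwrite = TRUE)

# 2. pair the per-wrist CSVs, synchronize, and segment one recording
pairs <- pair_recordings(list.files(dir, pattern = "sens[12]\\.csv$",
                                    recursive = TRUE, full.names = TRUE))$pairs
rec <- synchronize(read_recording(pairs$dominant[1]),
                   read_recording(pairs$non_dominant[1]),
                   stroke_type = "backhand", skill_label = "elite")
seg <- segment_recording(rec)
length(seg$windows)
#> [1] 20
seg$threshold_used
#> [1] 20
```

The recording contained 3 warm-up + 20 protocol backhands; the first three
detected strokes are excluded, all 20 protocol impacts are found at the
primary 20 g threshold, and each window is centred so the impact peak sits
at sample 41.

```r
# 3. stack windows and compute the bilateral asymmetry index
tensor <- assemble_tensor(seg$windows, seg$meta)
asin_tbl <- asymmetry_index(tensor)
round(median(asin_tbl$asin), 3)
#> [1] 0.069
```

An elite backhand is nearly symmetric (both hands drive the stroke), hence
the low median asymmetry.

```r
# 4. handcrafted features and top discriminative channels
demo <- simulate_windows(60, cfg, seed = 7)   # 60 windows per class
feats <- extract_all(demo)
dim(feats)
#> [1] 120 210
head(mi_ranking(feats, demo$meta$skill), 3)
#> # A tibble: 3 × 3
#>    rank feature             mi
#>   <int> <chr>            <dbl>
#> 1     1 F1_kurtosis      0.469
#> 2     2 F2_kurtosis      0.439
#> 3     3 F2F8_correlation 0.379
```

The most informative features sit on the dominant-wrist accelerometer
channels (F1–F3) and the bilateral pairs — amateur pre-impact fluctuation
flattens the peaky amplitude distribution (kurtosis) and decouples the
two wrists (correlation).

```r
# 5. group statistics (peak magnitudes in g)
group_summary(demo)
#> # A tibble: 8 × 7
#>   stroke_type skill       n dominant_mean dominant_sd non_dominant_mean
#> 1 backhand    amateur    20          31.6        3.61              21.5
#> 2 backhand    elite      20          35.6        1.66              26.6
#> 3 forehand    amateur    20          35.2        4.37              16.8
#> 4 forehand    elite      20          38.0        1.67              22.8
#> 5 service     amateur    10          38.2        3.73              14.8
#> 6 service     elite      10          43.2        1.84              22.0
#> 7 volley      amateur    10          31.1        2.07              10.8
#> 8 volley      elite      10          34.0        1.56              14.5
```

Elite cells show higher mean peaks with *smaller* SDs — the
consistency signature the classifier exploits. For model training and
evaluation see `?cross_validate`, `?train_model` and the methods vignette
(`vignettes/strokesense-methods.Rmd`); `tidy()`, `glance()` and
`autoplot()` methods are provided for fitted models, CV results, ANOVA
tables and PAM scores. A thin CLI lives in `inst/cli/strokesense`
(`strokesense run --config cfg.yaml --seed 1 --out DIR`).

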