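---
title: "Classifying perceived exertion from smartwatch telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying perceived exertion from smartwatch telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exertr)
```

## The problem

During a long run to volitional exhaustion, a runner's *rating of perceived
exertion* (RPE, Borg 6–20 scale) rises while heart rate drifts upward at a
constant workload (cardiovascular drift). RPE is informative for training
prescription but is reported sparsely and unreliably. `exertr` implements a
pipeline that estimates a binary exertion class from 1 Hz smartwatch
telemetry — heart rate (bpm), step cadence (steps/min) and running velocity
(m/s) — with the class boundary at the Borg score 15:

* `non_exerted` ("Somewhat hard to hard"): RPE ≤ 15;
* `exerted` ("Hard to very hard"): RPE > 15.

The study design the pipeline mirrors has two groups of six runners each.
Trained runners report RPE every 5 km (long runs, ~110 min, ~4.2 m/s);
untrained runners every 1 km (~75 min, ~2.9 m/s). That yields roughly 112
labels in total for a twelve-runner cohort, with both classes represented.

## From sparse labels to training windows

Each reported score at time $t$ is treated as constant within a maximal
temporal offset $m_o$ of the report, so every sample $t'$ with
$|t' - t| \le m_o$ inherits the report's binarized label. Within a labeled
range, every contiguous window of length $L$ seconds (stride 1, half-open
$[s, s+L)$ on the 1 Hz grid) becomes one training instance in
$\mathbb{R}^{L \times 3}$. The defaults are $m_o = 180$ s and $L = 60$ s,
so an interior marker whose range is not truncated by the session bounds
contributes exactly $2 m_o + 2 - L = 302$ windows.

Two numerical decisions are worth making explicit:

* **Overlap resolution.** With 1 km report intervals an untrained runner's
  reports arrive roughly every 6 minutes, so adjacent propagation ranges can
  overlap by a few seconds. Each timestamp is assigned to its *nearest*
  marker, ties to the earlier one; a genuine conflict (two different-label
  reports both within $m_o$) is logged as a warning.
* **Scaling.** Channels are z-normalized per runner using mean and
  *population* standard deviation over the full session. This removes
  between-runner offsets (resting heart rate, preferred cadence) so that
  distances compare shapes rather than levels. Because the statistics are
  session-level rather than training-fold-level, a small amount of
  information from a runner's full session reaches their own test windows;
  no information crosses runners, which is the leakage that matters under
  runner-level cross-validation. Channels with zero variance (a perfectly
  constant velocity) map to zeros rather than NaN.

The Borg baseline needs raw bpm, so each window carries its un-normalized
heart-rate segment alongside the z-scored values.

`extract_windows()` accepts a `stride` argument that keeps every
`stride`-th window start. The default (1) reproduces the "every possible
subsequence" definition; the heavier test and acceptance runs in this
package use strides of 30–80, leaving roughly 400–1,200 windows per cohort,
which preserves every marker and both classes while keeping DTW-based
evaluation tractable on a single CPU.

## The classifier roster

All seven classifiers sit behind one `fit_classifier()` /
`predict_classifier()` contract over labeled windows. Every tie anywhere in
the package resolves to `non_exerted`, the more frequent class, except kNN
ties, which go to the single nearest neighbour's label.

* **Majority vote** predicts the most frequent training label.
* **Borg rule**: the Borg scale was constructed so that RPE ≈ HR/10 for
  young adults. The classifier averages the window's raw heart rate,
  divides by ten, and predicts `exerted` iff the score strictly exceeds 15
  (continuous comparison, no rounding, mirroring the ≤ 15 labeling rule).
* **kNN + DTW** uses *dependent* multivariate dynamic time warping: one
  warping path shared across the three channels, local cost the squared
  Euclidean distance across channels, full dynamic program with no warping
  window. Votes may be uniform or inverse-distance weighted. With $k$
  equal to the training-set size and uniform weights the classifier
  provably reduces to the majority baseline.
* **SFA bag-of-words**: each channel is summarized by the real and
  imaginary parts of its first non-DC Fourier coefficients (an implicit
  low-pass filter) and quantized symbol-by-symbol with equi-depth bin
  edges learned from training data only (multiple coefficient binning).
  Channel-tagged words over word lengths `MinF:MaxF` form a bag-of-words
  vector classified by ridge logistic regression (cross-entropy loss).
  This is deliberately a single-word-length simplification of the
  WEASEL+MUSE family: no bi-grams, no chi-squared feature selection, no
  window-length ensembling.
* **SVM**: RBF kernel on the flattened $L \times 3$ window. A
  time-series-specific kernel would be a drop-in replacement via the
  `kernel` hyperparameter; the flattened-RBF choice is the declared
  default.
* **CNN and GRU** are served by a compact neural engine written in plain R
  matrix arithmetic. The CNN stacks `n_conv_layers` blocks of
  [1D convolution (kernel width 5, valid padding) → batch normalization →
  ReLU or SeLU], then global **max** pooling over time and a dense softmax.
  The GRU is a single recurrent layer with linear (input) and recurrent
  dropout — variational-style masks shared across time steps — feeding a
  dense softmax. Both train with Adam (learning rate $10^{-3}$),
  categorical cross-entropy, mini-batches of 32, at most 100 epochs, and
  early stopping with patience 10 on a 10% stratified validation split,
  restoring the best weights. The analytic gradients (including batch
  normalization and backpropagation through time) are verified against
  numerical differentiation in the test suite, and training is fully
  deterministic given a seed on a single thread.

Default hyperparameter search spaces are declared in
`default_search_space()`: $k \in \{1,3,5,7\}$, uniform or inverse-distance
weighting; $C$ log-uniform in $[10^{-2}, 10^{3}]$ and RBF $\gamma$
log-uniform in $[10^{-4}, 10]$; `MaxF` ∈ {4, 6}, `MaxS` ∈ {4, 8};
filters ∈ {16, 32, 64}, depth ∈ {2, 3}, activation ∈ {ReLU, SeLU};
units ∈ {16, 32, 64}, dropouts ∈ {0, 0.2, 0.5}.

## Evaluation design

Cross-validation is at the *runner* level, never the window level. A fold
plan partitions the twelve runners into six folds of two, each fold
containing exactly one trained and one untrained runner; identifying a fold
by its trained member shows there are $6! = 720$ admissible plans. For each
test fold, hyperparameters are chosen by random search scored with a
constrained 5-fold inner cross-validation over the ten remaining runners
only — the inner score is mean *window-level* accuracy, the simplest
reading of averaging fold accuracies, so model selection never sees a test
runner. The whole procedure is repeated over an odd number of repetitions
(the study design uses 15; the bundled runs use 3–5), with fold plans drawn
without replacement from the 720.

Window-level predictions are reduced to one prediction per original
(runner, marker) label by majority over that label's windows, then, across
repetitions, the modal class becomes the consensus prediction — the odd
repetition count makes ties impossible. Metrics are the standard accuracy,
precision, recall and F1, per class and support-weighted; support-weighted
recall is algebraically identical to accuracy, which doubles as an internal
consistency check on every report.

Classifier pairs are compared with the continuity-corrected (Edwards)
McNemar statistic on the consensus predictions,
$Z = (|C_{01} - C_{10}| - 1)^2 / (C_{01} + C_{10})$, rejected when $Z$
exceeds the $\chi^2_1$ quantile (3.841459 at $\alpha = 0.05$). When the two
classifiers disagree nowhere the statistic is defined as 0 with a warning.
No multiple-testing correction is applied across pairs.

## The synthetic cohort

No runner data ship with the package; `simulate_cohort()` generates
cohorts with the statistical structure the pipeline assumes:

* duration drawn per runner from the group distribution (trained
  110 ± 13 min, untrained 75 ± 14 min);
* constant self-selected velocity plus GPS jitter (trained 4.2 m/s,
  untrained 2.9 m/s, between-runner SD 0.3 m/s);
* heart rate as a saturating ramp in elapsed-run fraction between
  `hr_start_frac` and `hr_end_frac` of the runner's HRmax (defaults
  0.70→0.92 trained, 0.74→0.95 untrained, saturating at 90% of the run),
  plus noise, clipped to physiological range — the simplest model of
  cardiovascular drift at constant pace;
* constant cadence plus noise;
* RPE rising linearly from 9 at the start to 19 at exhaustion, with
  Gaussian noise before rounding, reported at each completed 1 km
  (untrained) or 5 km (trained) of cumulative distance.

These defaults reproduce the cohort's aggregate structure: about 112
reports in total, a ~6 min untrained and ~20–24 min trained inter-report
cadence, and a roughly 60/40 class split. One seed governs everything
through per-runner substreams, so the same seed is bit-identical and adding
a runner does not perturb the others.

`borg_exact_config()` constructs a noiseless calibration cohort in which
the heart-rate ramp crosses 150 bpm at exactly the run fraction where the
latent RPE crosses the 15/16 boundary, with enough slack that no window
within $m_o$ of a marker straddles the crossing. On this cohort the Borg
rule is exact — its cross-validated consensus accuracy is 100% — which
pins down the whole chain (propagation, extraction, CV, vote aggregation)
end to end. On the default *noisy* cohort, DTW+kNN consistently beats the
majority baseline with the McNemar test rejecting at $\alpha = 0.05$.

What the generator does *not* emulate: VO2 kinetics, lactate dynamics,
terrain and pacing variation, sensor dropout, or runner-specific HR–RPE
dissociation. Passing tests on synthetic cohorts therefore demonstrate
that the pipeline recovers the signal it models — monotone drift linked to
rising exertion — not that any particular accuracy carries over to real
runners.

## Worked example

```{r pipeline, eval = FALSE}
cfg <- run_config(
  cohort = cohort_config(seed = 11),
  classifiers = c("majority", "borg", "knn_dtw"),
  n_repetitions = 5, window_stride = 40,
  search_spaces = list(knn_dtw = list(k = 5L, neighbor_weighting = "uniform")),
  seed = 11)
bundle <- cmd_evaluate(cfg)
metrics_table(bundle$metrics)
bundle$mcnemar
```

## Known limitations

* The SFA classifier is a simplification; on real data the full
  WEASEL+MUSE feature set would likely perform better.
* Session-level scaling is a deliberate, documented leakage of a runner's
  own future statistics into their test windows (see above).
* The neural engine is CPU-bound and single-threaded; it is sized for the
  window dimensions used here, not for large-scale training.
* Report-table rounding is half-away-from-zero at one decimal; consensus
  metrics are the headline numbers, with per-repetition accuracies also
  emitted since either convention is defensible.
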