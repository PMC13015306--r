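---
title: "Respiration cycle features and single-trial outcome decoding: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiration cycle features and single-trial outcome decoding: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The analysis

breathdecode links breathing to trial-by-trial behavior in task-based
physiology experiments. The input is a continuous respiration voltage trace
(a nasal thermocouple sampled at 1 kHz; exhalation warms the sensor, so the
raw polarity is exhalation-up) together with a per-trial event table (trial
start, fixation onset, go cue, outcome in {correct, false_alarm, miss},
difficulty rank). The pipeline conditions the trace, segments it into breath
cycles, extracts a fixed 12-dimensional feature vector from the first
complete cycle after each trial start, compares features between correct and
incorrect trials at the session level, and decodes single-trial outcome from
the feature matrix.

Because real recordings of this kind are rarely shareable, the package ships
a first-class synthetic-data generator with *planted*, known,
outcome-dependent effects. Every downstream claim the test suite makes is a
parameter-recovery or calibration statement against that ground truth.

# Signal conditioning

The conditioning chain is: zero-phase 3rd-order Butterworth bandpass
(0.1–0.5 Hz, the dominant respiration band at roughly 15 breaths/min),
optional notch filters (off by default; mains frequencies can be supplied),
polarity inversion so that rising phases are inhalation, and session-wide
z-scoring (the thermal sensor has no absolute amplitude calibration, and
probe placement varies across sessions).

Two numerical choices matter here:

* **Second-order sections.** At 1 kHz the band edges are 2·10⁻⁴ and 10⁻³ of
  Nyquist; the expanded transfer-function form of this filter is singular in
  double precision (its output is NaN). The filter is therefore designed as
  an analog Butterworth prototype, bandpass-transformed, and bilinearly
  mapped pole-pair by pole-pair into a cascade of biquads. The cascade
  reproduces the analytic magnitude response to six significant digits
  (verified in the test suite against a closed-form oracle written
  independently of the design code).
* **Zero-phase application.** Filtering runs forward and backward with
  odd-reflection padding, so extremum times carry no group delay; the
  effective attenuation is the squared single-pass response. The padding is
  six periods of the low band edge (60 s): the slowest filter mode has a time
  constant of a few seconds, and this padding keeps startup transients below
  10⁻⁶ inside the data. Recordings shorter than the padding are rejected
  with the minimum length in the error message. Trials in the first or last
  seconds of a session remain edge-affected; the generator therefore pads
  sessions with 20 s of plain breathing on both sides.

`condition_signal()` also retains a lightly filtered companion trace
(0.05–2 Hz, same inversion and scale). The narrowband trace defines *which*
extrema exist; the wide trace is used only to refine *when* they occur (next
section).

# Cycle segmentation

Peaks of the conditioned trace mark exhalation onsets and valleys mark
inhalation onsets. The detector is deliberately simple and fully
deterministic:

1. candidate strict local extrema;
2. enforcement of strict peak/valley alternation (the most extreme member of
   any same-type run survives);
3. iterative removal of extrema with topographic prominence below
   `min_prominence` (default 0.3 z-units) and of same-type neighbours closer
   than `min_separation` (default 1.0 s, half the fastest in-band period),
   re-alternating after each removal;
4. assembly into valley → peak → valley cycles; unpaired leading/trailing
   extrema are discarded.

**Two-stage timing refinement.** A 0.4 Hz-wide passband cannot track
breath-to-breath period jitter at the sample level: on synthetic data the
narrowband extremum times err by tens of milliseconds, strongly correlated
with local cycle duration. Each extremum time is therefore re-localized on
the wide-band companion trace within ±`refine_window` (default 0.4 s) of the
narrowband extremum, with a final three-point parabolic sub-sample step.
With this two-stage scheme the detected inhalation onsets match the
generator's ground truth with a median absolute error below 20 ms at the
default noise level, against the 50 ms acceptance bound. Setting
`refine_window = 0` recovers a pure narrowband detector.

A session with no detectable extrema returns an empty cycle list plus a
quality-control flag rather than an error.

# Trial-aligned features

For each trial, features come from the *first complete cycle whose
inhalation onset is at or after trial start* (a cycle starting exactly at
trial start counts, ≥ convention). The canonical 12-vector, in fixed order:

* timing — inhalation onset latency, exhalation onset latency, inhalation
  duration, exhalation duration, respiration length (valley-to-valley;
  additivity `length = inhalation + exhalation` holds exactly by
  construction and is asserted anyway);
* amplitude — inhalation depth and exhalation depth (topographic prominences
  of the cycle's valley and peak), inhalation volume, exhalation volume,
  total volume. Volumes are magnitudes of the trapezoidal integral of the
  conditioned signal over each sub-interval after subtracting the
  sub-interval's chord, so slow residual drift does not masquerade as
  volume; magnitudes rather than signed areas are reported because the
  sensor is uncalibrated. Peak-to-peak cycle length is an equivalent
  estimator of the same quantity; the valley-to-valley definition is
  canonical here because the trial cycle itself is defined
  valley-to-valley;
* phase — instantaneous phase at trial start and at fixation onset, read
  from the angle of the analytic signal (FFT half-spectrum Hilbert
  transform) of the *whole-session* conditioned trace, in degrees wrapped to
  (−180, 180], 0° at exhalation onset and ±180° at inhalation onset. The
  FFT input is continued by odd reflection to a 5-smooth length (mixed-radix
  FFTs of awkward prime lengths are quadratic in R).

Trials with no complete cycle before the end of the recording keep their row
with `valid = FALSE`; a session with more than 20% invalid rows is flagged.

# The synthetic generator

The generator emulates a paced detection task: trial start → fixation
acquisition (truncated normal, 321 ± 57 ms) → fixation hold (uniform
400–600 ms) → delay to the go cue (exponential, rejection-truncated to
1.7–3.0 s; the exponential's rate is solved numerically so the *truncated*
mean equals the configured 2.0 s) → outcome-dependent ending. Outcomes are
i.i.d. (0.70 correct / 0.19 false alarm / 0.11 miss by default); false
alarms break fixation before the go cue and have no go-cue time. The next
trial begins 0.99 / 1.62 / 2.00 s (± 0.06 s jitter) after the
response/break/cue for correct / false alarm / miss respectively. An
optional per-difficulty detection-probability vector makes the psychometric
hit-rate curve recover those probabilities exactly in expectation.

Breathing is a train of asymmetric raised-cosine half-waves: inhalation
occupies 45% of each cycle (so inhalation and exhalation durations are
genuinely distinct features), the period is 4 s plus N(0, 0.25 s) jitter,
amplitudes jitter around 1 with the inhalation half-wave rising from the
previous cycle's trough so the trace stays continuous. The raw recording is
the negated trace (thermocouple polarity) plus slow sinusoidal drift
(≤ 0.03 Hz) and white noise (SD 0.1 by default).

**Planted effects and local re-timing.** At every trial start the ongoing
cycle is closed at `trial_start + U(1.0, 2.0)` s — the breath train is
locally re-timed so the next inhalation onset falls in that window. On
correct trials that onset is additionally moved by
`effect_inhalation_onset_shift`, the cycle starting there is lengthened by
`effect_cycle_length_delta`, and its amplitude raised by
`effect_amplitude_delta`. The narrow latency window is a deliberate design
choice with two motivations: it models breathing loosely entrained to a
self-paced task (trials tend to begin shortly after an inhalation), and it
is what makes a −0.3 s planted shift recoverable to ±0.05 s from a few
thousand trials (with latencies uniform over a whole 4 s cycle the
difference-of-means estimator would need an order of magnitude more trials).

Because trial spacing (~4–5 s) is close to the breath period, a trial's
feature cycle is usually still in progress when the next trial starts; the
next trial's re-timing then truncates it. Consequences, all recorded in the
ground truth:

* the onset shift is planted *exactly* for every trial;
* the length delta is carried into the truncated boundary, so it survives
  in expectation for every trial, while the exact drawn period survives only
  on non-truncated trials (flagged per trial);
* truncated cycle lengths inherit the outcome-dependent trial spacing, so
  under the null configuration respiration length retains a small structural
  outcome dependence (~0.15 s) even with all planted effects at zero. This
  mirrors a real property of such tasks — outcome-dependent inter-trial
  intervals couple task timing into any cycle-spanning measure — and it is
  why the type-I-error calibration of the outcome tests is run on directly
  simulated null features rather than on generator output.

Determinism: each session uses a child seed derived from the master seed by
a fixed linear-congruential step (kept below 2³¹), so session *i*
regenerated alone is bit-identical to session *i* of a batch.

# Outcome statistics

"Incorrect" pools false alarms and misses throughout. Session-level
comparisons are two-sided Wilcoxon signed-rank tests on per-session
(correct-mean, incorrect-mean) pairs — exact null distribution for n ≤ 25
without ties, normal approximation with continuity and tie correction
beyond; at least 6 sessions are required because p < 0.05 is unattainable
below that; all-zero differences are reported as p = 1 with a `degenerate`
flag. Within-session comparisons are two-sample t-tests on trial values
(pooled variance by default, Welch via `var_equal = FALSE`). No
multiple-testing correction is applied across the 12 features by default
(per-feature p-values are reported); Holm is available via
`compare_features(p_adjust = "holm")`. Phase features are compared with
circular means and a seeded label-permutation test (10,000 permutations by
default) on the absolute circular mean difference — a distribution-free
choice in the absence of a reason to assume a parametric circular model.
The signed-rank implementation is checked against an exhaustive 2ⁿ
enumeration oracle for n ≤ 10, and both tests are calibrated (3–7% rejection
at α = 0.05 over 500 null replicates).

# Decoding

The feature matrix stacks all valid trials (invalid rows dropped with a
logged count); labels are correct = 1 vs incorrect = 0. Choices that matter:

* **Class balance.** The ~70/30 outcome imbalance puts the base rate near
  the accuracies of interest, so the default protocol subsamples the
  majority class (seeded) before cross-validation; unbalanced mode remains
  available. Accuracy is pooled trace/total over held-out folds, and AUC is
  computed from pooled positive-class scores with a *fixed* orientation
  (never auto-flipped, which would bias null AUCs upward).
* **No leakage.** Per-feature z-scoring moments are computed on each
  training partition and applied to its test partition; test-fold columns
  are not expected to have zero mean, which the tests assert on a
  deliberately shifted fold.
* **Schemes.** Stratified five-fold CV with an inner stratified 4-fold
  hyperparameter search on each training partition, and leave-one-session-out
  with tuning on the remaining sessions. All stochastic components derive
  per-fold child seeds from one pipeline seed.
* **Model zoo.** Gradient-boosted trees (trees {100, 300}, depth {2, 3, 5},
  learning rate {0.05, 0.1}), random forest (300 trees, mtry {2, 3, 6}),
  RBF-SVM (C {0.1, 1, 10}, kernel width by the 1/d heuristic), KNN
  (k {5, 15, 31}, odd so binary votes cannot tie), and a single-hidden-layer
  MLP (16 or 64 units, weight decay 0.01). The grids are small and fixed on
  purpose: reproducibility at desk scale outweighs squeezing accuracy.
  `tune = FALSE` uses each spec's default row; sweeps accept a reduced grid.
* **Feature importance** is gradient-boosting gain, normalized to sum to 1,
  zeros for features the booster never used, ties resolved by canonical
  order.
* **Exhaustive subset sweep** evaluates all C(p, k) subsets per k with folds
  fixed across subsets (accuracies are comparable), first-in-lexicographic-
  order tie-breaking for the best set, and a combinatorial guard at 14
  features.
* **Trial-history control** refits on trials whose predecessor (within
  session) was correct, dropping each session's first trial; **subject
  pooling** concatenates per-subject matrices, keeping subject id strictly
  as bookkeeping.

# Problem sizes and what the tests show

The test suite and acceptance script run at desk scale, chosen as the
smallest sizes at which each claim's tolerance is a ≥3σ statement: 40
sessions × 40 trials for detection recovery; 12–20 sessions × 150 trials
(≥ 1800 trials) for shift recovery at ±0.05 s; 500 replicates for test
calibration; 20 seeded label permutations × 5 models for decoder null
calibration; 10 sessions × 120 trials for the planted-effect decoding and
LOSO comparison; 200 trials × all 4,095 subsets (KNN, default parameters)
for the sweep.

Passing on synthetic data shows that the pipeline is *correct and
calibrated*: it recovers what was planted, rejects at nominal rates when
nothing was, and is bit-reproducible under a fixed seed. It does not show
that real respiration obeys the generator's assumptions — real traces
contain sniffs, apneas, sipping artifacts, amplitude nonstationarity and
history-dependent breathing, none of which are modeled (artifact rejection
beyond flatline detection is explicitly out of scope). Two quantified
caveats from the synthetic studies themselves: band-limited timing
measurement attenuates planted group differences by roughly 4–5%
(regression of extremum estimates toward the local rhythm), and truncated
cycle lengths inherit a small outcome dependence from the task's
inter-trial-interval structure, so cycle-length effects on real data should
be interpreted jointly with trial timing.
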