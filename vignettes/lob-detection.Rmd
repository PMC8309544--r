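---
title: "Detecting loss-of-balance events in real-world walking data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting loss-of-balance events in real-world walking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Loss-of-balance (LOB) events — trips, slips, stumbles that would end in a
fall without a recovery response — are rare, short (mostly 1–3 s, under
7 s in the data regime this package targets) and scattered through
multi-hour days of unscripted activity. Recording them requires only three
wearable inertial measurement units (IMUs): one on each foot and one on
the lower trunk, each measuring tri-axial acceleration (m/s²) and angular
rate (deg/s) at 128 Hz, with axes x = anteroposterior,
y = mediolateral, z = longitudinal. Finding the events afterwards is the
hard part: at a ~1:1500 positive:negative window ratio, a classifier's
job is not fully automatic labeling but *data reduction* — discarding the
overwhelming majority of windows so a human reviewer inspects only
plausible candidates, while missing as few true events as possible.

`lobdetect` implements that pipeline end to end: kinematic
reconstruction, gait feature extraction, window labeling, imbalance-aware
classifier training with leave-one-participant-out (LOSO) validation, and
window- plus event-level evaluation. Because no public dataset with
annotated real-world LOB events exists, the package also ships a
first-class synthetic cohort generator with ground-truth events; every
quantitative claim the test suite makes is made against that generator.

## Kinematic reconstruction

Foot trajectories come from classic strapdown integration with
zero-velocity updates (ZUPT):

1. **Stance detection.** A sample is provisionally stationary when the
   gyro magnitude is below ω_thr = 20 deg/s and the accelerometer
   magnitude is within 0.5 m/s² of g = 9.80665 m/s². The provisional mask
   is opened with a 0.1 s sliding test window (removing spurious
   sub-window runs without eroding true stance plateaus) and stance
   intervals shorter than 0.1 s are dropped. All four thresholds are
   arguments of `detect_stationary()`.
2. **Orientation.** Quaternion integration of the gyro with the midpoint
   (RK2) rule, initialized by aligning the mean specific force of the
   first stance interval with gravity. No magnetometer is used; heading
   is arbitrary, which is harmless because every downstream feature is a
   length, duration, magnitude or trunk pitch/roll quantity —
   i.e., heading-invariant (a property the tests check explicitly).
3. **Velocity and position.** World-frame acceleration = rotated specific
   force minus gravity; trapezoidal integration to velocity; within each
   inter-stance segment the velocity drift is removed by subtracting the
   linear ramp that forces velocity to zero at the two bounding stance
   phases; stance samples are pinned to zero; position is re-integrated.
   A Kalman-filter ZUPT would be the natural upgrade; the interface
   isolates the correction so one can be substituted without touching the
   rest of the pipeline.
4. **Strides.** One footfall per stance interval, placed at the interval
   midpoint; one stride per consecutive same-foot footfall pair. Stride
   length is the horizontal-plane displacement between footfalls; peak
   swing velocity is the maximum speed between them.

Trunk pitch (about the mediolateral axis) and roll (about the
anteroposterior axis) come from a complementary filter fusing gyro
integration with the accelerometer gravity tilt, coefficient 0.98 at
128 Hz (≈0.16 s time constant). Pitch rate is read from gyro y and roll
rate from gyro x, which is what those gyro axes physically measure under
the stated axis convention. Trunk yaw is never estimated — no feature
uses it.

## Windows, features, labels

Each recording day is segmented into 10 s windows every 2 s
(`windowing_config()`), so consecutive windows overlap by 8 s and any
event shorter than 8 s is fully contained in at least one window —
provided it ends before the last window does; trailing partial windows
are discarded. A window is labeled positive when its half-open interval
intersects any annotated event interval, however marginally.

Every window gets a 32-entry descriptor (`lob_feature_names()`): a binary
gait indicator (1 when the window holds ≥ 5 strides longer than 0.1 m),
total walked distance, seven-number summaries (max, min, mean, median,
IQR, variance, RMS) of stride length and stride time, per-foot maximum
and mean speed, per-foot swing-velocity statistics, and trunk RMS
pitch/roll plus angular-velocity RMS and range. Conventions that needed
fixing:

* A stride belongs to every window containing its footfall-to-footfall
  midpoint time, so assignment is unambiguous at window boundaries.
* Quartiles (median/IQR) use the linear-interpolation convention
  (R's `quantile` type 7), frozen in the tests.
* Windows with no strides get zeros for all stride statistics rather than
  missing values, so the classifier sees the entire day, non-gait
  included; trunk statistics are always computed.
* Features are z-scored per fold using training-subject windows only.
  The upstream description is silent on standardization; regularized
  models need a common scale for the penalties to be meaningful, and
  fold-local constants avoid test-subject leakage.
* The source material states both "32" and "34" features in different
  places and never names the extra two; this package implements exactly
  the 32 named ones, so the flattened 11-step linear input has
  352 entries rather than 374.

## Classifiers

Examples are **context sequences**: the feature vectors of windows
t−5 … t+5 (11 steps, 22 s of context), labeled by the center window. Edge
windows without a full context are dropped, not padded — padding would
fabricate kinematics, and the loss is ten windows per day.

Two architectures are provided:

* `lob_logistic()` — penalized logistic regression on the flat 352-entry
  vector, minimizing mean binary cross-entropy
  + l1·‖w‖₁ + l2·‖w‖₂² (fit via glmnet's elastic net with
  λ = l1 + 2·l2, α = l1/λ, an exact reparameterization).
* `lob_bilstm()` — a bidirectional LSTM written for this package in
  RcppArmadillo: forward and backward LSTMs (default 2 cells each) read
  the 11 steps, their final hidden states are concatenated into a single
  dense sigmoid unit. Training is Adam (lr 1e-4), 50 epochs, batch 256,
  with the same L1/L2 penalties on input, recurrent and dense weights
  (biases exempt). Gradients are exact BPTT, verified in the test suite
  against finite differences at 1e-6 tolerance. Under a strong L1
  penalty the all-zero weight vector is a stationary point of the
  objective (a dead model emitting a constant 0.5); if training
  converges there — detectable as a final balanced loss pinned at
  log 2 with vanishing weights — the fitter re-initializes with a
  seed-derived restart (up to 5), keeping the fit deterministic.

Class imbalance is handled by up-sampling positives to exact 1:1 balance:
whole duplication cycles plus a seeded remainder draw, re-drawn each
epoch for the BiLSTM; negatives are never subsampled. All training is
deterministic given a seed (one `std::mt19937` drives initialization,
shuffling and up-sampling), and repeated runs are bit-identical on one
platform.

`run_loso()` wires the protocol: for each of the 8 folds, the held-out
subject contributes to neither feature standardization nor training;
`select_hyperparameters()` implements the inner LOSO grid search over
l1, l2 ∈ {1e-5 … 1e-1} and cells ∈ {2, 5, 10}, minimizing mean validation
cross-entropy with ties broken toward larger penalties, then fewer cells.
The default model settings (logistic: l1 0.01, l2 1e-5; BiLSTM: 2 cells,
l1 0.1, l2 0.001) are the selected configurations for this problem and
are representable grid points.

## Evaluation

* **AUROC** by the rank-statistic (Mann–Whitney) formulation, ties ½.
* **AUPR** as step-wise (non-interpolated) average precision — linear
  interpolation in PR space is biased, so it is deliberately avoided.
* **Bootstrap CIs** from 200 seeded resamples of the held-out subject's
  windows (degenerate single-class resamples are redrawn and counted).
  Resampling windows-within-subject matches the window-level metrics; an
  alternative — resampling days or cross-validation trials — would widen
  the intervals and is noted as an open design alternative.
* **Event-level metrics** at threshold 0.5: data reduction = share of
  windows predicted negative; sensitivity = share of merged events with
  at least one predicted-positive overlapping window; precision = share
  of predicted-positive windows overlapping any event. The window-level
  precision numerator is the convention consistent with sub-1%
  precisions at realistic imbalance; an event-count numerator could not
  produce such values.
* **Grouped permutation importance** over six feature groups (walked
  distance; stride length; stride time; trunk angles/velocities; swing
  and foot velocity; gait indicator): each group's columns are permuted
  jointly across examples — the same permutation at all 11 context
  steps — and the AUROC/AUPR drop is averaged over 10 seeded repeats.
  Grouping correlated features avoids the dampening that per-feature
  permutation suffers when the information survives in correlated
  columns.
* **Model comparison** over the 8 per-fold AUROCs uses a two-sided paired
  Wilcoxon signed-rank test (exact for tie-free differences). The test
  identity is a package decision: the upstream description reports a
  significance level without naming a test, and the signed-rank test is
  the standard paired nonparametric choice at n = 8.

## The synthetic cohort generator

`simulate_cohort()` emulates the study regime the pipeline assumes, with
defaults frozen as the package's study conditions:

* 8 subjects; per-subject event-day counts (10, 5, 1, 1, 5, 3, 2, 4) and
  event counts (23, 8, 1, 2, 18, 3, 2, 5) — 31 event-days, 62 events.
* Day length ~ normal(11.4 h, 1.8 h) truncated to 6–16 h.
* Walking occupies ~12% of each day, in bouts of 30–120 s alternating
  with rest bouts whose durations are derived from the walking fraction.
* Subject gait baselines: stride time ~ normal(1.1 s, 0.05 s), stride
  length ~ normal(1.25 m, 0.08 m); within a bout strides fluctuate with
  AR(1) correlation 0.3 (SDs 0.08 s and 0.10 m).
* Trunk sway during gait: sinusoidal pitch (step frequency) and roll
  (stride frequency) with 2° RMS baseline plus noise.
* Events: durations 80% uniform(1, 3) s and 20% uniform(3, 7) s, placed
  strictly inside walking bouts with a 30 s minimum gap (so merged-event
  semantics are trivial in default cohorts).
* Event effects, lasting through the event and the following two
  strides: stride length × 0.5, trunk angular-velocity range × 4, trunk
  sway RMS × 2. The velocity and angle multipliers are reconciled by
  doubling both the sway amplitude and its frequency during the event —
  a compensatory rapid trunk rotation — which keeps the tier-2 inverse
  kinematics self-consistent (the gyro really is the derivative of the
  angle stream).
* Seed hierarchy: master → per-subject → per-day, so any subject-day
  regenerates independently and bit-identically.

Walking fraction, bout ranges, AR(1) correlation, within-subject SDs,
sensor noise (accel σ 0.02 m/s², gyro σ 0.2 deg/s) and biases
(0.01 m/s², 0.02 deg/s — post-calibration consumer-IMU scale) are not
given by the upstream description; the values above were chosen once as
field-plausible and are config-overridable but not tuned.

The generator has two tiers. Tier 1 emits stride tables and trunk
streams (8 Hz) directly — fast enough to simulate full 11-hour days.
Tier 2 (`inverse_imu_from_day()`) synthesizes raw 128 Hz recordings by
analytic differentiation of piecewise trajectories (zero-velocity stance,
cycloidal swing arcs with a 25° peak foot-pitch excursion and 5 cm foot
lift, both profiles chosen C¹ in rate/acceleration at the swing edges so
sampled signals integrate without systematic per-stride error)
plus noise and bias, and exists to exercise the ZUPT kinematics: the
round trip from stride table through raw signals back to stride table
recovers walked distance within 5% over a minute of gait (typically
within 1%).

What the generator does *not* emulate — and hence what passing tests do
not show about real data: biomechanically realistic trip/slip dynamics
(effect sizes are stand-ins, declared as such in provenance output),
turning and stair gait, sensor mounting artifacts, magnetic disturbance,
non-walking dynamic activities that mimic gait, and annotation timing
error. On the synthetic cohort the classes are cleanly separable and the
BiLSTM reaches near-perfect AUROC; real-world performance is necessarily
lower, and the synthetic results should be read as validating the
pipeline's plumbing and training machinery, not as a performance claim
for real data.

## Scaled-down evaluation cohort

The end-to-end LOSO check runs on a reduced cohort: day length fixed at
1 h and per-subject event counts multiplied by the day-length ratio
(1/11.4), floored at one event per subject so every held-out subject
remains evaluable at the event level (`scale_gen_config()`). Exact
incidence preservation is impossible under that floor (10 events over
31 one-hour days gives ≈ 1:880 instead of ≈ 1:1600); the floor was chosen
because an unevaluable fold is worse than a modest incidence shift. With
8 subjects × ~1,790 windows/day this keeps the full 8-fold, 50-epoch
BiLSTM protocol under ten minutes on one CPU; the full-length cohort is
used where only labels are needed (the imbalance-regime check, three
seeds, ~640k windows each).

## Numerical choices and degenerate inputs

* Gravity 9.80665 m/s²; all angles in degrees at the interface, radians
  internally.
* Probabilities are clamped to [1e-12, 1−1e-12] inside the
  cross-entropy, so the loss is finite; a non-finite training loss aborts
  with the epoch index.
* Constant features in a training fold standardize to zero (scale forced
  to 1) instead of exploding; an all-constant design matrix short-circuits
  the logistic fit to the penalized intercept-only optimum.
* Variance of a single stride is reported as 0, matching the
  zero-for-degenerate convention of the stride statistics.
* LSTM weights initialize uniform ±sqrt(6/(fan_in+fan_out)) with
  forget-gate bias 1; Adam uses β = (0.9, 0.999), ε = 1e-8.
* `upsample_balance()` with positives ≥ negatives returns the data
  unchanged; zero positives is an error, not a silent fallback.

## Known limitations

* Orientation is never re-corrected during long integrations; tier-2
  checks run on minutes of gait, where gyro-noise drift is negligible.
  Hour-scale raw integration would need stance-phase tilt resets.
* The linear inter-stance de-drift is a simplification of filter-based
  ZUPT; residual intra-stride velocity error is absorbed into stride
  length, bounded by the 5% round-trip test.
* The bootstrap unit (windows) understates between-day variability for
  subjects with few days.
* The bidirectional architecture needs the five windows *after* an event,
  so detection lags real time by ≥ 20 s by design; the intended use is
  retrospective review, not alarms.
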