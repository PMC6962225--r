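---
title: "Hierarchical assessment of resting tremor and bradykinesia from a wrist accelerometer: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wristmotor methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

A wrist accelerometer records everything the hand does. A resting-tremor
measure is only meaningful while the hand is at rest; a bradykinesia
measure (slowness, smallness, poverty of voluntary movement) is only
meaningful while the hand is moving voluntarily and the movement is not
walking, since arm swing during gait says nothing about upper-limb
bradykinesia. `wristmotor` therefore decides context first and scores
symptoms second. Errors propagate down the hierarchy by design: a rest
window misread as movement can never be scored for tremor. We accept this
rather than smooth it away; an optional three-window median filter over the
hand-movement labels exists (`smooth_labels = TRUE` in `run_visit()`) but
is off by default, because removing isolated windows trades sensitivity for
specificity and that trade-off belongs to the analyst.

## Windows and units

Everything operates on 3-second, non-overlapping windows at 128 Hz
(384 samples). Three seconds resolves tremor (fundamental typically
3–8 Hz, so ≥ 9 cycles per window) and spans several steps at a normative
cadence above 102 steps/min. Acceleration is in g, angular velocity in
deg/s, time in seconds from recording start. Windows are half-open sample
ranges `[start, start + 384)`; a trailing partial window is dropped, never
padded, so visit aggregates are duration-weighted over full windows only.
All "majority" rules are strict: a window covered for exactly half its
duration is negative.

## Hand-movement detection

Vector magnitude (orientation-free), sixth-order Butterworth low-pass at
3 Hz (removes tremor-band oscillation), rolling coefficient of variation
over a trailing 1-s span, threshold 0.01, per-window strict majority vote.
The rolling span is trailing with stride one sample; the first 127 samples
take the first full-span value. The coefficient's denominator is the
low-passed vector magnitude, which sits near 1 g at rest, so no recentering
is needed; an ε = 10⁻⁶ guard covers pathological near-zero means.

## Zero-phase filtering

All filters are Butterworth IIR designs applied forward–backward
(zero-phase). Processing is offline, and per-window phase distortion would
bias the RMS and jerk measures; the cost is a doubled effective order and a
squared magnitude response, which is what the test suite's frequency-response
checks target. Two implementation details matter on 3-s windows:

* each pass is initialized at the step steady state of its first sample,
  so a gravity-dominated signal (mean ≈ 1 g) has no startup transient;
* edges are padded by odd reflection, up to one second, because a 0.25 Hz
  band edge settles over ~0.6 s.

Even so, the band-passes used for feature extraction are applied to the
*continuous recording* before windowing (the matrix and pipeline paths do
this; the per-window entry points remain for closed-form checks). Filtering
each 3-s window separately leaves slow baseline wander whose size depends
on how the waveform's phase falls against the window grid; we observed this
as a periodic beat in the gait-periodicity features before moving filtering
to the stream level.

## Feature catalogs

The gait catalog (47 features) derives from 4 processed signals — the three
axes band-passed at 0.25–3.0 Hz (first order) and their per-window first
principal component — with 11 statistics each (mean, SD, coefficient of
variation, RMS, range, IQR, skewness, kurtosis, dominant frequency,
relative power in 0.5–3.0 Hz, spectral entropy) plus 3 cross-signal
features: mean pairwise inter-axis correlation, the lag-constrained
autocorrelation peak of the PCA signal, and the cadence that lag implies.
The tremor catalog (64 features) uses 8 processed signals — axes plus PCA
in each of the non-tremor (0.25–3.0 Hz) and tremor (3.5–7.5 Hz) bands —
with 8 statistics each (RMS, variance, range, zero-crossing rate, dominant
frequency, power at the dominant frequency, relative tremor-band power,
spectral entropy). Catalogs are fixed name registries
(`gait_feature_names()`, `tremor_feature_names()`), so an alternative list
can be swapped in without touching the pipeline.

Spectra are Hann-tapered periodograms at the native 1/3 Hz resolution, no
zero-padding, scaled so total power equals the taper-corrected window
variance; spectral entropy is Shannon entropy of the normalized spectrum
over 0–64 Hz, divided by log(#bins) to lie in [0, 1].

Two catalog choices were genuinely open and deserve their rationale:

* **PCA per window, not per recording.** Per-window fitting is robust to
  posture changes within a visit; the sign is fixed (non-negative loading
  on the highest-variance channel) for determinism.
* **Periodicity lags 0.3–1.5 s.** At the wrist, arm swing at half the step
  rate dominates, so gait periodicity appears at the *stride* time
  (~1.05–1.2 s at normative cadence) as well as the step time. The
  autocorrelation peak is searched over 0.3–1.5 s among true local maxima,
  with the triangular (n-divisor) estimator bias undone so long lags
  compare fairly on 3-s windows; lags beyond 0.75 s are read as stride
  periods when converting to steps/min.

## Classifiers: balancing, selection, forest

Both trainable stages share one pipeline: seeded undersampling of the
majority class, recursive feature elimination with a decision-tree learner
and cross-validated selection of the retained set, then a ten-tree random
forest (ten trees; clinical validation of this approach found no gain
beyond ten, and the count is configurable). Two selection details are our design:

* **Folds group whole subjects** whenever at least as many subjects as
  folds are present. Row-level folds let a feature that is only valid for
  one device orientation look perfect; subject-grouped folds demand that a
  feature set generalize across subjects.
* **Ties go to the larger set.** Elimination continues to a single feature,
  and the retained set is the one with the highest cross-validated
  accuracy, resolving exact ties toward more features. On cleanly separable
  data a tie chain otherwise collapses the catalog to one feature whose
  in-sample perfection does not survive a new subject.

Gait training labels come from task annotations: windows majority-covered
by a gait task are positive, mixed carrying tasks can be excluded, the rest
are negative. Tremor training labels come from a gyroscope heuristic
applied to PD recordings (positives) and *all* healthy-control windows
(negatives). Leave-one-subject-out evaluation rebuilds balancing, selection
and training from scratch with the held-out subject removed, so no
information can leak; a corruption test asserts this.

## The gyroscope labelling heuristic

The gyroscope algorithm originally used to generate tremor labels is
proprietary in its details, so a three-criterion surrogate stands in,
clearly labelled as such: a window is
tremor when (a) the dominant frequency lies in 3.5–7.5 Hz, (b) the
tremor-band RMS of the band-passed angular-velocity vector magnitude is at
least 1.5 deg/s, and (c) tremor-band power is at least 2.5 times the
0.5–3 Hz movement-band power. All thresholds live in the configuration.
One correction to the obvious implementation: the vector magnitude of a
zero-mean oscillation is full-wave rectified, which doubles its dominant
frequency out of band, so the spectral criteria are computed on the sum of
per-axis power spectra — a rotation-invariant quantity without the
rectification artifact.

## Severity measures

* **Tremor amplitude** per window: third-order 3.5–7.5 Hz band-pass of the
  raw tri-axial window, vector magnitude, RMS (g). A vector-magnitude
  envelope A yields A/√2, verified against the closed form.
* **Visit tremor summary**: constancy = 100 × (tremor windows)/(all visit
  windows); the denominator is all windows by default with a rest-only
  switch. Visit amplitude = 85th percentile (linear interpolation between
  order statistics) of per-window amplitudes over *tremor-flagged* windows;
  flagged-only is the default because unflagged windows would dilute a
  severity measure, and the all-windows reading remains available as a
  switch. The percentile, not the maximum, mimics the examiner's "largest
  amplitude observed" while resisting outliers.
* **Bradykinesia** per eligible window (hand movement present, gait absent,
  not in the scripted-task exclusion mask): RMS amplitude and scaled mean
  squared jerk of the 0.25–3.5 Hz band-passed vector magnitude. Jerk is the
  first forward difference times the sampling rate; the mean square is
  scaled by T²/max(s)², making the measure dimensionless,
  amplitude-invariant and monotone in frequency — a pure smoothness index.
  The exact normalization was open; it is isolated in one function.
* **Visit bradykinesia summary**: mean amplitude, 95th percentile of the
  jerk measure, percent of analyzed time with no hand movement, and mean
  no-movement bout length (maximal runs of no-movement windows; exclusions
  break runs and truncated bouts count at observed length). No eligible
  windows means *missing*, never zero, with a machine-readable flag.
* **Clinical score model**: ordinary least squares of the 0–12 hand
  bradykinesia score on the single retained predictor, mean movement
  amplitude, with predictions clipped to [0, 12] and leave-one-subject-out
  RMSE reported. Longitudinal mixed-effects modelling of these measures
  retains exactly one sensor feature as predictor; estimating subject
  random effects adds nothing to a fixed-effects predictor evaluated by
  LOSO, so the affine model is the deliberate simplification here.

## Agreement statistics

Kruskal–Wallis (tie-corrected, χ² approximation) and the paired Wilcoxon
signed-rank test wrap the stats implementations; zero differences are
dropped (Wilcoxon's convention) and the exact distribution is used up to 25
untied differences. For paired ON/OFF comparisons the signed-rank test is
the statistically correct choice, and it is what `wilcoxon_paired()`
implements; a rank-sum test would ignore the pairing.
Conover–Iman post hoc statistics use the standard tie-corrected form with
the (N−1−H)/(N−k) variance adjustment, referred to t on N−k degrees of
freedom, with Benjamini–Hochberg correction across all pairs. Linearly
weighted Cohen's kappa uses weights |i−j|/K on the full ordinal range.
ICC(A,1) — two-way model, absolute agreement, single rater — is computed
from the ANOVA mean squares with the McGraw–Wong F-based confidence
interval, and is cross-checked in the tests against hand-computed tables
and a known-variance-ratio simulation.

## The synthetic-signal generator

No clinical recordings accompany the package, so a seeded generator
produces the four signal classes the method assumes, with per-sample
ground truth:

* **REST**: a randomized gravity unit vector plus white noise
  (σ = 0.002 g by default, per-subject 0.0015–0.003 g in cohorts).
  Healthy-control subjects additionally carry *physiological tremor* in the
  gyroscope (1.2–3 deg/s at 6.5–8 Hz, amplitude-modulated, with a tiny
  0.002 g-per-deg/s accelerometer counterpart): this is what makes a
  threshold gyroscope heuristic produce false positives in controls, the
  behavior the machine-learning stage is meant to improve on.
* **TREMOR**: an amplitude-modulated sinusoid at the scripted fundamental
  (3–8 Hz; cohorts draw 4–6.5 Hz) whose device-frame direction drifts
  slowly, as pronation–supination tremor does under small posture shifts.
  Cohort severity is log-uniform over 0.02–0.3 g — barely perceptible to
  overt — and the gyroscope amplitude is tied to it (100 deg/s per g), so
  weak tremor is weak in both modalities and the learning problem is
  realistically hard rather than trivially separable.
* **MOVE**: voluntary movement as a band-limited stochastic trajectory
  (0.3–2.5 Hz) plus a weaker rhythmic component whose tempo wanders by
  ~25 %; hesitancy (`jerkiness` ∈ [0, 1]) adds rapid corrective
  accelerations near the top of the movement band and partial halting
  bursts, raising the jerk measure monotonically. Movement directions keep
  a substantial gravity-parallel component, because real wrist movement
  tilts the device through the gravity field; purely gravity-orthogonal
  acceleration (invisible to the vector magnitude) is not representative.
* **GAIT**: cadence-periodic step impulses along gravity plus an arm-swing
  harmonic at half the step rate. Cohorts randomize cadence
  (100–125 steps/min), step-impulse (0.2–0.4 g) and swing (0.08–0.25 g)
  amplitudes per subject; a fixed swing amplitude would hand the classifier
  an amplitude shortcut that no real cohort offers.

Segments crossfade over 0.25 s; state durations bookkeep exactly; a single
base seed drives everything through a documented counter scheme
(`derive_seed()`), so cohorts are reproducible and extensible.

What the generator does **not** emulate: soft-tissue and mounting
resonances, device drift and temperature effects, dyskinesia, kinetic or
postural tremor, real activity-of-daily-living diversity, annotation and
clock misalignment. Passing tests on this generator therefore demonstrate
that the pipeline recovers what it is designed to recover under its own
signal model — context paths, constancies, amplitudes, monotonicities —
not that clinical accuracies would match on real data: reported clinical
validations of this kind of hierarchy (≈93 % hand-movement accuracy,
≈96 % gait accuracy, ≈83 % tremor accuracy) rest on private clinical
datasets and video annotation.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which the statistics are stable: training cohorts of
5 HC + 10 PD subjects with 3-minute visits, a 20-minute scripted clinic
visit (400 windows) for context recovery, 10-subject cohorts with 5-minute
visits for the gait leave-one-subject-out evaluation, and 1000 replicates
for type-I-error simulations. The scripted visit's reach segments use
movement parameters representative of the PD severity distributions
(slow, small, hesitant movement); the generator's neutral single-segment
defaults describe an idealized smooth mover that no cohort subject
resembles. Percentiles interpolate linearly between order statistics
(quantile type 7). Degenerate inputs fail loudly and specifically:
zero-variance PCA windows, single-class training sets, missing gyroscope,
all-zero Wilcoxon differences, zero between-subject ICC variance.

## Known limitations

Tremor assessment requires the hand-at-rest gate, so tremor during
voluntary movement is invisible by construction. The gyroscope surrogate is
not the original reference algorithm; its thresholds are configurable but
uncalibrated against clinical data. The 85th/95th visit percentiles are
fixed defaults (they were originally calibrated against clinical scores in
5 % increments from the 80th to the 95th; that selection loop is out of
scope here). The feature catalogs are a reconstruction matching the
documented counts and signal structure, not a verbatim feature list. The
affine score model ignores subject-specific intercepts and covariates, and
amplitude in g is not mapped onto the ordinal 0–4 clinical scales.
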