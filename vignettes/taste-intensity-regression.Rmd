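---
title: "Recognizing taste-stimulus intensity from facial sEMG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing taste-stimulus intensity from facial sEMG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgtaste)
```

## The problem

When a tastant touches the tongue, facial muscles respond involuntarily —
most visibly to unpleasant (negative-hedonic) tastes: the depressor anguli
oris trembles at the mouth corner, the procerus frowns, the levator labii
superioris quivers the upper lip. Surface electromyography (sEMG) over
these muscles records that response non-invasively. `semgtaste` implements
a pipeline that turns six-channel facial sEMG recordings made under
stimuli of the five primary tastes (Sour, Sweet, Bitter, Salty, Umami) at
six intensity levels each into a quantitative estimate of stimulus
intensity, via support-vector regression.

Each taste is presented as a dilution series: the series maximum carries
an integer *strength label* of 5 and every half-order-of-magnitude
dilution drops the label by 1, down to 0 for deionized water. Two
alternative label schemes are supported: the *relative concentration*
(concentration over the series maximum, linear in concentration) and the
subject's own 0–10 *scale score*.

## Pipeline

1. **Windowing.** Each 12 s trial is cut into 1 s windows advanced by
   0.25 s (45 windows per trial), all channels sliced identically.
2. **Baseline removal (QVR).** Baseline wander — slow, large-amplitude
   drift from facial movement and device zero drift — is removed by
   quadratic variation reduction: the smooth component `s` solving
   `(I + λ DᵀD) s = x` (with `D` the first-difference matrix) is
   subtracted from the raw window `x`. The system matrix is symmetric
   positive-definite tridiagonal and is solved in linear time through a
   sparse factorization. `λ = 2` by default: large enough that the
   smoother tracks only sub-EMG-band trends at a 1000 Hz rate, while
   `λ → ∞` degenerates to mean removal and `λ = 0` removes everything.
3. **Adaptive notch.** Mains interference appears at 50 Hz and integer
   harmonics. Per channel, each harmonic bin of the window's discrete
   spectrum is compared with the median magnitude of its flanking bins
   (offsets 3–8 bins); only when the peak exceeds `detect_ratio = 5`
   times that median is the harmonic treated as interference, in which
   case the magnitudes in a ±1-bin notch are replaced by linear
   interpolation of the flanking medians, phases kept, and the window
   rebuilt by the inverse transform. Clean spectra pass through
   essentially unchanged — that is the "adaptive" contract. Windows where
   the notch removed more than 80% of total spectral power on any channel
   are rejected as unrecoverably distorted. Both thresholds are
   configurable; the defaults were fixed once, before any model fitting,
   as round values that separate the synthetic generator's mains-dominated
   windows from its clean ones by two orders of magnitude.
4. **Features.** Per channel, 55 features: the 0–499 Hz magnitude
   spectrum summed over fifty 10 Hz bands (band *n* covers
   `[(n−1)·10, n·10)` Hz — a disjoint partition, so the fifty sums equal
   the total spectral magnitude exactly); the spectral moments FC
   (centroid), RMSF (root-mean-square frequency) and RVF (root-variance
   frequency), which satisfy `RMSF² = FC² + RVF²`; and the time-domain RMS
   and MAV. Six channels give a 330-vector, channel-major, named
   `f001..f330`.
5. **Regression.** Epsilon-SVR with an RBF kernel, five-fold
   cross-validation, scored by the coefficient of determination R².
   Features are standardized per training fold (never on the held-out
   fold). Hyperparameters default to `C = 1`, `ε = 0.1`, `γ = 1/d` on
   standardized features — the conventional libsvm-style heuristics, fixed
   in `cv_spec()` and recorded in every result object; no tuning loop is
   run.
6. **Channel-wise feature selection.** Within each channel the 55
   features form 11 ordered groups of five. Starting from the empty set,
   the group maximizing CV R² of the augmented set is added each round
   (66 fits per channel in total), giving an R²-vs-NF curve at NF = 5,
   10, …, 55. The *inflection point* is the largest NF whose R² is within
   0.02 of the curve maximum — past it, extra features cost more than they
   bring. The union over channels of the groups retained at each
   channel's inflection is the reduced feature set; its dimensionality is
   the sum of the per-channel inflection NFs.
7. **Muscle activity maps.** For every (taste, intensity, channel) cell
   the mean spectral amplitude integral (the full 0–499 Hz magnitude sum;
   identical to the sum of the fifty band features) summarizes muscle
   activity; each cell is normalized by the same channel's intensity-0
   value, so water is exactly 1 everywhere. Channel 1 is excluded from the
   maps: it is a differential pair on the right masseter, and channel 6 —
   a single electrode on the left masseter — represents that muscle more
   directly. `activity_heatmap()` renders the grid with a sequential
   light-to-dark scale.
8. **Cohort analysis.** For a subject pool, the model is refit on every
   nonempty subject subset (31 for five subjects) and the mean R² per
   subset size NS is the R²_NS curve; with heterogeneous subjects the
   curve typically falls as NS grows.

## The synthetic generator

No public recordings accompany this problem, so the package ships a
seeded generator whose output has the statistical structure the analysis
assumes, making every downstream stage testable:

- **Carrier.** Gaussian white noise band-limited to 20–450 Hz (the
  standard sEMG energy band) in the frequency domain and normalized to
  exact unit RMS, then scaled per channel by
  `carrier_rms · (1 + slope(ch) · hedonic(taste) · intensity)`. Default
  baseline RMS is a nominal 20 µV. The slopes are largest on channel 2
  (depressor anguli oris, 0.60) and channel 5 (procerus, 0.50), matching
  the qualitative ordering of facial responses to unpleasant tastes;
  `hedonic` is 1 for Sour/Bitter/Salty and 0 for Sweet/Umami by default,
  so positive-hedonic tastes produce intensity-flat signals.
- **Baseline wander.** Five random-phase sinusoids below 2 Hz plus a slow
  ramp, total amplitude 200 µV — ten times the carrier RMS, so baseline
  removal has real work to do.
- **Mains.** A 50 Hz sinusoid with harmonics at amplitudes 30/9/3 µV.
- **Seeding.** Every trial's signal is a pure function of
  (stimulus, subject, config, seed). Dataset generation derives per-trial
  seeds by hashing the master seed with the trial coordinates, so any
  single trial can be regenerated independently of generation order.
- **Scores.** The simulated 0–10 self-report is linear in the intensity
  index (0 → 0, 5 → 10) plus Gaussian noise (sd 1.0 by default,
  reflecting how subjective such scoring is), clamped to the scale.

What the generator does *not* emulate: motor-unit physiology, electrode
geometry and skin impedance, inter-channel correlation of genuine facial
expressions, non-stationarity within a trial, or inter-subject
variability beyond a per-taste gain. Passing tests on synthetic data
therefore demonstrate that the pipeline's machinery is correct and
recovers planted structure; they do not certify the R² levels attainable
on real recordings, which depend on physiology the generator deliberately
leaves out. On the default synthetic Salty series the regression is far
cleaner (CV R² ≈ 0.99) than any real facial recording would allow.

## Numerical and design choices

- The band partition starts at DC: band 1 covers 0–9 Hz. After QVR the
  DC bin is essentially zero, so this choice is immaterial in practice
  but keeps the partition exact.
- The spectrum is the unnormalized one-sided FFT magnitude with no taper.
  Scale factors cancel in every scale-invariant statistic downstream
  (moments, R² on standardized features, normalized activity); band
  features and RMS/MAV scale linearly with signal amplitude, as tested.
- All-zero windows have undefined spectral moments; they are returned as
  `NA` with a warning rather than silently coerced to 0.
- Greedy selection breaks R² ties by the lowest group index; the addition
  rule always adds the group that achieved the best score.
- QVR is applied per channel independently; the operator is defined on a
  single signal, and matrix input is handled column-block-wise through
  one factorization.
- Whether to notch before or after baseline removal is an open ordering
  question; the default is QVR first, then notch, matching the order in
  which the two artifacts are usually illustrated (baseline first).
- Five-fold CV shuffles at the window level by default, mirroring the
  original analysis; because overlapping windows from one trial are
  correlated, this is optimistic, and a `grouping = "trial"` mode keeps
  whole trials within folds for a leakage-free estimate. Shuffling is not
  stratified by intensity.
- Fits performed by `fit_cv()` are counted in a package-local counter so
  procedures with an exact expected fit count (66 per channel in greedy
  selection, 31 for a five-subject cohort) can be audited.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on the
single-subject, two-session synthetic Salty series: 12 trials of 12 s,
540 windows, 330 features — enough samples for stable five-fold CV while
keeping a complete selection run (396 cross-validated fits) to tens of
seconds. Structural checks that do not depend on trial length (dataset
counts, the 150-cell activity grid) use 2 s trials.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config(seed = 42)
ds <- generate_dataset(subject_profile("s1"), sessions_per_subject = 2,
                       config = cfg, tastes = "Salty")
features <- process_dataset(ds)

fit <- fit_cv(features, "strength_label", cv_spec(seed = 42))
fit
#> <semg_cv> 5-fold sample-grouped CV on 540 samples
#>   fold R2: 0.990 0.992 0.994 0.994 0.995
#>   mean R2: 0.9930

sel <- select_features(features, cv = cv_spec(seed = 42))
plot_selection_curve(sel$traces)

act <- activity_table(features)
activity_heatmap(act)
```

## Limitations

- The synthetic conditions are deliberately favorable; real-data R²
  levels are far lower and subject-dependent.
- The notch operates on whole 1 s windows in the frequency domain; it is
  not a causal filter and is not meant for streaming use.
- Only the greedy grouped forward procedure is implemented — no
  recursive elimination or regularization-path alternatives.
- The cohort analysis pools subjects; it does not attempt cross-subject
  transfer or leave-one-subject-out generalization.
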