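---
title: "Methods: QEEG depression screening with normative z-scores"
author: "qeegscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QEEG depression screening with normative z-scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeegscreen)
```

## The screening problem

Resting-state EEG carries spectral signatures of depression: elevated fast
beta activity and reduced upper-alpha power. Because raw band power varies
strongly with sex and age, a screening model built on raw features confounds
demographics with pathology. The pipeline implemented here standardizes every
spectral feature against a sex- and age-stratified normative model before
classification, so that each feature expresses how far a subject deviates
from healthy peers of the same sex and age.

The full chain is:

1. **Cohort and signal synthesis** — seeded generators for a two-group study
   cohort (potential depression, defined by a Beck Depression Inventory
   cut-off of 14.48, vs. controls with BDI 0) and for a normative cohort
   spanning ages 4.5–81.
2. **Preprocessing** — 60 Hz notch and 1–45 Hz band-pass (zero-phase),
   common average reference (CAR), 4 s epoching with ±100 µV bad-epoch
   rejection, and ICA-based removal of blink and mains components.
3. **Spectral features** — Welch band power on the 8-band scheme
   (Delta 1–4, Theta 4–8, Alpha1 8–10, Alpha2 10–12, Beta1 12–15,
   Beta2 15–20, Beta3 20–30, Gamma 30–45 Hz), absolute (µV²) and relative
   (fraction of 1–45 Hz total).
4. **Normative z-scoring** — per (sex, channel, band, kind), a polynomial
   regression in age on a transformed scale, with constant residual spread.
5. **Group statistics** — normality-gated per-cell comparisons producing
   per-electrode significance tables and topographic summaries.
6. **Feature selection** — MSE-split importance from six tree ensembles;
   the final set is the intersection of each model's top-T features.
7. **Classification** — ten classifiers over a feature-count ladder with a
   stratified 80/20 split and 10-fold cross-validation on the training side.

The feature table holds 4 kinds × 7 bands × 19 channels = 532 columns
(`Abs`, `Rel`, `Abs_zscore`, `Rel_zscore`; gamma is excluded as a feature but
retained in the relative-power denominator).

## The synthetic world

No public data exist for this design, so the generators are first-class,
tested code. Their defaults *are* the stated study conditions:

* **Cohort** (`cohort_config()`): 116 potential-depression subjects
  (23 men, age 58.66 ± 15.08, BDI 21.17 ± 6.28 truncated above 14.48) and 80
  controls (44 men, age 48.66 ± 16.71, BDI 0). Sex counts are exact by
  construction; ages are truncated normals on [4.5, 81]. The source
  description is internally inconsistent about the depression group's sex
  split (its counts sum to 118, not 116); the group size is taken as
  authoritative and the female count is the complement (93).
* **Spectral targets** (`spectral_profile()`): per-channel absolute
  beta2/beta3 power (both groups) is taken directly from the published
  per-electrode group tables; per-channel total power is inferred from the
  absolute/relative beta pairs; absolute alpha2 follows from relative
  alpha2 × total; the remaining power is split over delta/theta/alpha1/
  beta1/gamma with fixed eyes-closed fractions (0.25/0.15/0.40/0.12/0.08 of
  the remainder — a posterior-alpha-dominant resting distribution), shared
  between groups. Depression scales alpha2 down by the channel-wise relative
  alpha2 ratio. Between-subject variation is log-normal with the tables'
  coefficients of variation (0.8 for uncalibrated bands).
* **Signals** (`generate_eeg()`): each band is independent brick-wall
  band-limited Gaussian noise scaled per subject to the drawn target power,
  plus a 1/f background, a mains sinusoid (60 Hz, South Korean mains), and
  biphasic ~0.4 s blink transients with a fixed frontal-dominant scalp decay
  (12/min, ~120 µV at Fp1/Fp2). This makes realized band powers directly
  controllable and calibration transparent.
* **Normative world** (`norm_trend_config()`): log10 band power drifts
  linearly with age (slow-wave and alpha decline ~0.003–0.006 log10/yr,
  beta rises slightly), women +0.05 log10, spread 0.30 log10 — magnitudes a
  practitioner would call realistic for maturational band-power trends.
  `generate_normative_powers()` draws feature values directly from this
  model (no time series), which is what the normative fit and its
  calibration tests consume; `generate_normative_cohort()` additionally
  synthesizes full recordings.

What the generator does **not** emulate: channel covariance (channels are
independent), within-subject nonstationarity, eyes-open states, volume
conduction, and realistic artifact diversity. A green test therefore
establishes that the *pipeline machinery* is correct and calibrated on its
stated world — not that the classifier would reach any particular accuracy
on clinical recordings.

## Numerical and design choices

* **Filters**: zero-phase Hamming-windowed-sinc FIR band-pass (0.5 Hz
  transition at the low edge) after a zero-phase biquad notch (Q = 30).
  Reflection padding controls edge transients. A finite transition band
  means content exactly at 1 or 45 Hz keeps losing a few percent on
  refiltering; idempotence is therefore exact only for in-band content, and
  the band-power estimates the pipeline consumes change by well under the
  few-percent level on refiltered data.
* **ICA**: deflation FastICA (tanh contrast) on PCA-whitened retained
  epochs. On this generator most directions are exactly Gaussian, hence
  unidentifiable — symmetric FastICA provably cannot converge there.
  Extraction proceeds one component at a time and stops at the first
  non-converging direction, leaving the Gaussian residual untouched; only
  extracted components are artifact candidates. Flagging: frontal
  squared-topography fraction > 0.6 AND sub-4 Hz spectral fraction > 0.5
  (blinks), or line-frequency peak ratio > 3 (mains). The frontal score uses
  squared weights because CAR adds diffuse compensating weights to every
  topography, capping the absolute-weight fraction near 0.55 regardless of
  how frontal a source is.
* **Welch PSD**: Hann-windowed per-epoch periodograms averaged over retained
  4 s epochs (0.25 Hz resolution); one-sided, µV²/Hz.
* **Band integration**: left-closed bins (`f_low ≤ f < f_high`, last band
  closed), i.e. a rectangle rule on the partition. This makes the 8 bands an
  exact partition of 1–45 Hz (relative powers sum to 1 to machine precision,
  Parseval holds) and fixes edge ownership: the 10 Hz bin is Alpha2.
* **Normative model**: degree-2 polynomial in age per cell, fit by least
  squares on log10 (absolute) or clamped logit (relative) scales; spread is
  the constant residual SD per cell. Age-dependent spread is not modelled
  (nothing in the source constrains it); scoring refuses extrapolation
  beyond the fitted range ± 2 years, and a sex with < 30 subjects or < 20
  years of age span is marked unfit.
* **Statistics gate**: Shapiro–Wilk for n ≤ 50, Lilliefors-corrected KS
  (Dallal–Wilkinson approximation) above; Welch's t only when *both* groups
  pass at α = 0.05, Mann–Whitney otherwise; two-sided, per-cell p < 0.05
  uncorrected (matching per-electrode starring), Benjamini–Hochberg behind
  a flag.
* **Ensembles**: depth-3 regression trees (compiled split search), 100
  learners, rate 0.1. LogitBoost, GentleBoost, AdaBoostM1 and bagging follow
  their published algorithms; RobustBoost and TotalBoost are config-flagged
  fallbacks (AdaBoost with per-subject weight capping at 4/n, and capped-
  simplex projection at 10/n respectively) — the downstream selection
  contract needs only each model's top-T ranking. Importance is the summed
  weighted-MSE split decrease divided by the ensemble's branch-node count;
  ties at rank T break by canonical feature-name order. One shared T for
  all models; `sweep_threshold()` finds, per target size, the smallest T
  whose intersection reaches it, truncating by mean rank.
* **Classifiers**: no SVM library exists in the target environment, so the
  SVM family is least-squares: RBF LS-SVM (median-heuristic bandwidth,
  C = 1) for `SVM`, a degenerate single-machine wrapper for binary `ECOC`,
  L2-regularized linear least-squares for `rSVM`, and random Fourier
  features (D = 200) + ridge for `GK`. `DA` is linear discriminant analysis,
  `KNN` k = 5 on standardized features, `NB` Gaussian naive Bayes, `DT` a
  single depth-10 tree, `LB`/`AdaM1` 100 stumps at rate 0.1. All
  deterministic given seeds.
* **Evaluation**: one shuffled stratified 80/20 partition (floor rounding;
  196 subjects → 39 test) shared by every grid cell; 10-fold stratified CV
  loss on the training side; depression is the positive class; the best
  cell maximizes test accuracy with ties broken by minimal CV loss.
  Selection defaults to leakage-safe mode (importance fit on the training
  partition only); `paper_mode = TRUE` reproduces whole-data selection.

## Calibration facts worth knowing

With ~200 normative subjects per sex, a fitted cell's mean curve carries an
irreducible level error of about σ/√200 ≈ 0.07σ, so *individual* cells'
held-out z means scatter by roughly ±0.07 even when the model family is
exactly right; calibration is therefore judged on the distribution of
per-cell moments (centred at 0 and 1), not cell by cell.

Under the log-normal world at the published per-channel effect sizes, the
normality gate routinely routes cells to Mann–Whitney, whose per-cell power
at n = 116/80 spans roughly 0.3–0.9 across the starred cells; detection
fractions should be read against that spread.

## Limitations

The synthetic world is deliberately minimal; absolute classification
accuracies on it say nothing about clinical performance. RobustBoost and
TotalBoost are approximations by fallback. The EDF I/O supports the
package's own 16-bit, one-second-record files, not the full EDF+ zoo.
Scalp maps use crude inverse-distance interpolation meant for orientation,
not publication graphics.
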