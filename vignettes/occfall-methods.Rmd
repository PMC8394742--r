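---
title: "One-class classifiers for wearable fall detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-class classifiers for wearable fall detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occfall)
```

## The problem

A wearable fall detection system watches a waist-worn triaxial
accelerometer and must raise an alarm when the wearer falls, while staying
quiet through ordinary Activities of Daily Living (ADLs). Supervised
classifiers need labeled fall recordings to train on, which are almost
impossible to collect from the population that needs the device. One-class
classifiers (OCCs) sidestep this: they are trained **only on ADLs** and
flag any movement whose features diverge from that training distribution as
an anomaly — which, for a waist sensor, is a reasonable operational
definition of a fall.

This package implements that study design end to end: a synthetic trace
generator standing in for public fall/ADL repositories, peak-centered
feature extraction, five one-class scorers with a hyperparameter grid,
ROC-sweep evaluation with a geometric-mean optimal cut-point under
stratified 5-fold cross-validation, a majority-voting ensemble, and a
leave-one-activity-category-out ablation probing the classifiers' blind
spots.

## Signal model and features

Every trace is an $N \times 3$ sequence of acceleration components in g.
The per-sample signal magnitude vector

$$SMV_i = \sqrt{A_{x,i}^2 + A_{y,i}^2 + A_{z,i}^2}$$

is the workhorse statistic: at rest it sits at 1 g, dips toward 0 g during
free fall, and spikes at impact. Feature extraction keeps only a 2 s
observation window centered on the sample attaining the global SMV
maximum ($N_W = \mathrm{round}(2 f_s)$ samples at sampling rate $f_s$);
everything else in the trace is discarded. Two seconds comfortably brackets
the critical phase of a fall, whose impact spike rarely exceeds 0.5 s.

Two windowing corner cases needed a decision:

* A window "centered on the peak" cannot be honored verbatim when the
  peak sits within 1 s of a trace edge; the window is then shifted (not
  truncated) so it stays $N_W$ samples long and still contains the peak.
* Traces shorter than $N_W$ are edge-replicated up to the window length.
* Tied maxima resolve to the first occurrence, so extraction is
  deterministic.

Twelve candidate statistics (IDs A–L) are computed from the window: mean,
standard deviation, maximum (impact violence) and minimum (free-fall depth)
of SMV; the maximum sample-to-sample vector variation; the mean rotation
angle between consecutive acceleration vectors; the mean first difference
of SMV; the mean floor-parallel component; SMV skewness; the signal
magnitude area; total energy $\sum SMV_i^2$; and the mean autocorrelation
of the mean-removed SMV. The experiments use two presets: the compact
`BCDFGIK` subset and the full `ABCDEFGHIJKL` set.

Some of these statistics have competing definitions in the literature, so
the package fixes them explicitly: the rotation angle comes from
consecutive *accelerometer* vectors (no gyroscope is assumed, since several
public repositories lack one); the floor plane for feature F is defined by
the normalized window-mean acceleration, the simplest usable gravity proxy;
skewness is the uncorrected sample $g_1$ (0 for constant windows); the
autocorrelation in L is the biased normalized estimator averaged over all
positive lags (0 for constant windows); the standard deviation uses the
$N_W - 1$ denominator. These choices keep every feature finite on
degenerate inputs.

Features are z-score normalized with means and standard deviations fitted
**on the training partition only** and applied unchanged to test rows —
fitting on pooled data would leak test information into the scaler.
Near-constant columns (sd below $10^{-12}$) are centered but not scaled.

## The five one-class scorers

All five expose one contract: train on ADL rows, then score any row with
*larger = more anomalous*. Likelihood-style scores are negated to share
that orientation, so a single threshold sweep serves every model.

| Model | Natural score | Grid |
|---|---|---|
| Sparse autoencoder | reconstruction MSE | hidden neurons 6, 10, 12, 15 |
| Gaussian mixture (diagonal) | negative log-likelihood | 3, 5, 7 components |
| Parzen window (PPNN) | −likelihood, window $f(u)=e^{u-1}$ | single configuration |
| OC-KNN | distance to k-th neighbour | {euclidean, minkowski, chebychev, cosine} × k ∈ {5, 10, 50} |
| OC-SVM (ν = 0.05) | −decision value | {linear, quadratic, cubic, medium gaussian} |

Design notes, where the field leaves latitude:

* **Autoencoder.** One logistic-sigmoid hidden layer and a logistic-sigmoid
  output, trained full-batch with Adam for up to 1000 epochs on
  MSE + $0.001\,\|W\|^2$ + KL sparsity (coefficient 1, target mean hidden
  activation 0.05). Because a sigmoid decoder can only emit $(0,1)$,
  inputs are min–max scaled to $[0,1]$ inside the model using training
  ranges, and reconstruction error is measured in that scaled space.
* **GMM.** Hand-written EM with k-means++ initialization, a $10^{-6}$
  variance floor (duplicated feature rows would otherwise collapse a
  component), tolerance $10^{-6}$ on the mean log-likelihood, at most 500
  iterations. The per-iteration log-likelihood trace is retained and
  tested for monotonicity.
* **PPNN.** Bandwidth is not fixed by the window function alone; the
  default is the median pairwise training distance divided by $\sqrt2$,
  exposed as an argument.
* **OC-KNN.** The Minkowski exponent is 3 — exponent 2 would silently
  duplicate the separately listed Euclidean option.
* **OC-SVM.** $\nu = 0.05$ reflects clean ADL training sets. Kernel
  conventions follow the common toolbox naming: polynomial kernels
  $(x^\top y + 1)^d$ with $d = 2, 3$; "medium gaussian" is an RBF with
  kernel scale $\sqrt P$ for $P$ features. The quadratic programme is
  solved by `e1071::svm`.

## Evaluation protocol

**Threshold sweep.** For each trained model the test scores (reserved ADLs
plus all falls) are swept with 2500 linearly spaced thresholds spanning the
pooled score range; the rule *score ≥ τ ⇒ fall* makes the lowest threshold
attain sensitivity 1 and a sentinel beyond the maximum attain specificity
1, so the ROC runs from (1,1) to (0,0). AUC is the trapezoidal area; the
optimal cut-point $\tau^\*$ maximizes $G = \sqrt{Se \cdot Sp}$, taking the
smallest threshold on ties. Choosing $\tau^\*$ on the test fold mirrors the
protocol being reproduced and is deliberately optimistic; the per-fold
standard deviation of $G$ is reported alongside the mean to keep that
visible.

**Cross-validation.** ADLs are split into 5 partitions stratified by
activity type (each type shuffled under the run seed, then dealt
round-robin), so in the "fair" case every movement type appears in every
training set. Falls never enter training: each fold trains on 4/5 of the
ADLs and tests on the remaining fifth plus all falls. Grid winners maximize
the mean per-fold $G$, with ties broken by mean AUC and then enumeration
order — every tie-break in the package is "first in deterministic order".

**Ensemble.** The three best configurations vote with their own per-fold
thresholds; two or more votes make a fall.

**Ablation.** For each ADL intensity category (basic / standard /
sporting), the winner is retrained on the other two categories and tested
on the held-out category plus all falls, classifying with the fair-case
threshold — the median of the five per-fold $\tau^\*$ values, since a
single operating point must be distilled from five folds. The reported
*Loss* is $G_{\text{ablation}} - G_{\text{fair}}$.

## What the synthetic generator emulates — and what it does not

No public repository ships with this package; a seeded generator produces
traces with the structure the analysis depends on:

* gravity as 1 g along a per-subject orientation unit vector, with smooth
  (spherically interpolated) posture transitions so the rotation-angle
  feature is exercised;
* three ADL categories of increasing intensity: basic fluctuations of
  0.02–0.08 g with at most one posture transition; standard periodic
  movement at 1.5–2.5 Hz and 0.2–0.5 g with one harmonic; sporting
  movement at 2.5–3.5 Hz and 0.8–2.0 g with sporadic spikes up to 4 g;
* falls as four phases — pre-fall activity, a free-fall dip to a floor of
  0.1–0.4 g over 0.2–0.6 s, a half-sine impact spike of 3–6 g lasting at
  most 0.5 s (always the global SMV maximum), and rest at a new lying
  orientation;
* per-subject heterogeneity as a single amplitude multiplier in
  [0.8, 1.2] — the simplest mechanism that makes subject-blind folding
  meaningful;
* white Gaussian per-axis noise (default 0.03 g), since real sensor noise
  is not characterized in the sources the ranges were reconstructed from.

Amplitude and frequency ranges were chosen once, to land inside the ranges
the corresponding features are meant to capture and to preserve the
qualitative orderings the analysis relies on (falls out-peak basic ADLs;
SMV spread grows basic → standard → sporting). They are not fitted to any
real dataset. Consequently, passing results here demonstrate that the
*pipeline* behaves as designed — they do not certify performance on real
accelerometry, where class overlap is far larger, sampling rates vary
(18–238 Hz across public repositories), and ADL catalogues are richer. The
generator's separability is intentionally strong; the ablation stage is
where the synthetic conditions reproduce the interesting failure mode
(energetic movements trained out become false alarms).

## Numerical choices and degenerate inputs

* Unit conversion uses 9.80665 m/s² per g at read time; everything
  internal is in g.
* Trace CSVs are written with 12 significant digits, so a write/read
  round-trip is lossless to below $10^{-9}$ g.
* Score ties in the threshold sweep, peak ties in windowing and $G$ ties
  in the grid all resolve to the first candidate in deterministic order.
* Every stochastic component (generator, folds, k-means++, autoencoder
  initialization) is seeded; a fixed configuration reproduces identical
  trace files and an identical JSON report.
* Degenerate inputs are mapped to finite values rather than errors where a
  convention exists (constant windows: skewness, autocorrelation and
  rotation angle 0) and to clear errors where none does (empty manifests,
  sub-2-sample traces, k larger than the training set).

## Problem sizes

The shipped analysis and the acceptance script use the default study
conditions: 90 traces (20 ADLs per category + 30 falls) of 15 s at 100 Hz,
5-fold cross-validation, and 3–5 independently seeded replicate datasets
for the stochastic summaries. The unit-test fixtures are smaller (8 s at
50 Hz, 34 traces) to keep the suite quick while exercising identical code
paths.

## Known limitations

* The synthetic generator is a structural emulation, not a biomechanical
  model; absolute performance numbers on it exceed anything achievable on
  real repositories.
* The optimistic test-fold threshold selection inflates $Se$/$Sp$ relative
  to a deployment setting; an honest validation-split mode would be the
  natural extension.
* Feature definitions B, D, F, J and L follow reasonable reconstructions
  of their literature descriptions; other implementations may differ in
  detail.
* The HCTSA-style automatically selected feature set is out of scope; the
  feature-set argument accepts arbitrary custom ID subsets instead.
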