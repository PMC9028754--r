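---
title: "Methods: the analog GMM wake-up classifier, its behavioral circuit model, and the synthetic evaluation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the analog GMM wake-up classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmmwake)
```

## The problem and the system

Continuous EEG monitoring for epileptic seizure prediction must run for days
on a small battery. Digital inference engines accurate enough to be clinically
useful consume microwatts to milliwatts, which dominates the power budget of a
wearable. A *wake-up architecture* splits the job: an always-on, nanowatt
analog classifier watches the signal and switches on the accurate digital
back-end only when a seizure appears imminent. The front-end must be extremely
sensitive — a missed seizure is unacceptable — while its specificity directly
sets how often the expensive back-end wakes up, and therefore the total system
power.

`gmmwake` models this system end to end in software: the ideal Gaussian
mixture model (GMM) classifier, a behavioral model of its subthreshold analog
realization, the EEG feature pipeline that feeds it, the alarm-based
evaluation metrics, and synthetic data generators so that every stage can be
exercised and tested without clinical recordings.

## The ideal classifier

Each class $c \in \{1,\dots,C\}$ (here: pre-ictal vs inter-ictal) gets its own
mixture density over the $N$-dimensional feature vector $X$:

$$p(X \mid \lambda_c) = \sum_{i=1}^{K} w_i^c \, \mathcal{N}(X \mid M_i^c, \Sigma_i^c),
\qquad \sum_i w_i^c = 1,$$

with *diagonal* covariances, so each component factorizes into a product of
$N$ univariate Gaussians — the property that makes an analog realization by
cascaded one-dimensional circuits possible. All classes share the same
cluster count $K$; $K$ is a hyperparameter chosen for the complexity of the
data, not selected automatically. Classification is the likelihood argmax

$$y = \arg\max_{c} \; p(X \mid \lambda_c),$$

with ties broken toward the lowest class index (an explicit convention; the
probability of an exact tie is zero for continuous data, but the
deterministic rule keeps software and behavioral hardware bit-identical).

### EM fitting: numerical choices

`fit_em()` implements the expectation-maximization algorithm for
diagonal-covariance mixtures. The choices that the mathematics leaves open
are fixed as follows:

* **Initialization** — k-means seeding (`stats::kmeans`, 10 restarts) from a
  caller-supplied integer seed; responsibilities are then refined by EM. A
  balanced random partition is the fallback when the data have fewer distinct
  points than clusters (e.g. degenerate all-identical input).
* **Convergence** — stop when the relative log-likelihood change drops below
  `tol = 1e-6`, or after `max_iter = 500` iterations.
* **Variance floor** — fitted variances are clamped at `var_floor = 1e-6`
  (feature units squared). This prevents components collapsing onto single
  points; it also means features should be expressed on scales where real
  variation is well above $10^{-3}$ — the package convention is peak-to-peak
  amplitude in microvolts and band fractions in $[0,1]$.
* **E-step arithmetic** — carried out in the log domain with log-sum-exp, so
  4-D products of small densities cannot underflow.

The per-iteration log-likelihood trace is stored on the fitted object and is
asserted non-decreasing in the tests — the EM guarantee, checked on every
run. With $K = 1$ the M-step gives the closed-form Gaussian MLE (sample mean
and *biased* sample variance) after one iteration, which the tests check to
`1e-9`.

### Architecture accounting

The analog realization is controlled by one mean voltage $V_r$ and one width
voltage $V_c$ per univariate bump ($C K N$ of each) plus one bias current per
class: $2CKN + C$ parameters — 34 for the $C=2, K=2, N=4$ classifier. The
per-class (rather than per-cluster) bias current means the hardware ties
within-class cluster weights; the software mixture keeps free weights, and
the analog mapping offers a `tied_weights` mode that mirrors the hardware
exactly.

Operation counting uses a fixed convention chosen so that each univariate
Gaussian evaluation costs 8 scalar operations (difference, square, scale by
the precomputed inverse variance, halve, negate, exponentiate, scale by the
precomputed normalizer, multiply into the running product), cluster sums cost
$K-1$ additions per class, and the argmax costs $C-1$ comparisons:
$8CKN + C(K-1) + (C-1)$, i.e. 131 operations for the default architecture.
Other decompositions are defensible; this one is documented, fixed, and used
consistently by `count_operations()` and `accounting_report()`.

## The behavioral circuit model

The analog model is equation-level, not transistor-level: it captures the
functional behavior a circuit designer would verify by simulation, with no
transient dynamics (steady-state classification only).

* **Bump law** — a subthreshold bump circuit (differential pair plus current
  correlator) produces a Gaussian-like output current. We model it as
  $I(V_{in}) = I_{bias} \,\mathrm{sech}^2\!\big((V_{in}-V_r)/(2\,\kappa U_T\, w(V_c))\big)$,
  the classic differential-pair response, with $U_T = 25.85$ mV,
  slope factor $\kappa = 0.7$, and rails at $\pm 0.3$ V. The sech² curve fits
  a Gaussian with $R^2 \approx 0.996$ over $\pm 4$ effective standard
  deviations, which the test suite asserts across the whole calibration grid.
* **Width map** — the variance control is modeled as
  $w(V_c) = \exp((V_c - c_0)/c_1)$ with $c_0 = 0$ V, $c_1 = 0.3$ V: positive,
  smooth and monotone. Because no closed form ties $V_c$ to the *fitted*
  Gaussian width, `calibrate_width()` calibrates numerically: it fits a
  unit-peak Gaussian to the bump at each grid $V_c$ and builds interpolating
  forward/inverse maps (effective $\sigma \approx 0.78 \cdot 2\kappa U_T
  w(V_c)$, roughly 10–77 mV over the default $\pm0.3$ V grid). Width requests
  outside the calibrated range are clamped with a warning.
* **Cascade** — biasing bump $n{+}1$ with bump $n$'s output multiplies their
  curves, so a cluster of $N$ cascaded bumps realizes the diagonal-covariance
  product; `multivariate_bump()` uses the closed-form product, which the
  tests verify against an explicit stage-by-stage cascade to `1e-9` relative
  on random configurations.
* **Class summation and WTA** — current mirrors add cluster outputs
  (`class_current()`); a winner-take-all stage picks the largest class
  current. The ideal WTA gives the winner the full bias current and losers
  exactly zero; the contract in any mode is losers below 100 pA ("logical
  zero"). An optional finite-gain soft mode exists but is off by default.

### Mapping a trained GMM onto the circuit

`map_gmm_to_analog()` needs three conventions the mathematics does not fix:

* **Feature conditioning** — a per-dimension affine map of the training
  data's [1st, 99th] percentile range onto $[-150, +150]$ mV, keeping bump
  centers and almost all inputs inside the rails with headroom. Inputs
  outside the rails are clamped, with a warning.
* **Heights** — the first-stage bias current is proportional to the cluster
  weight, normalized so the largest cluster current is a configurable full
  scale (12 nA default, matching the demonstration bias of the bump). The
  per-cluster Gaussian normalizers $\prod_n (2\pi \sigma_n^2)^{-1/2}$ are
  *not* folded in: this is the distortion inherent in the height-as-weight
  hardware convention, and it is why analog and ideal decisions are compared
  statistically (the tests require $\ge 95\%$ agreement on separated data and
  100% where the likelihood ratio exceeds 10) rather than exactly.
* **Tied weights** — `tied_weights = TRUE` forces equal within-class bias
  currents, the hardware-faithful mode implied by one bias current per class.

### Mismatch Monte-Carlo

Process variation is abstracted as independent Gaussian perturbations of each
bump: additive $V_r$ offset ($\sigma = 2$ mV), multiplicative width gain
(2%) and multiplicative bias-current gain (2%) — typical subthreshold
matching scales, fully configurable, and *not* calibratable from any single
published histogram since the mapping from process parameters to these three
knobs is our abstraction. Each run's perturbation is a pure function of
`(seed, run_index)`, so distributed or resumed sweeps reproduce exactly.
`monte_carlo_eval()` reports the per-run specificity distribution with its
mean and standard deviation; with all sigmas zero it reproduces the
unperturbed specificity in every run, exactly.

## The feature pipeline

Four features per analysis window: peak-to-peak amplitude and the fractions
of total spectral power in the alpha band and the lower and upper halves of
the gamma band. The conventions, all configurable:

* **Band edges** — alpha 8–13 Hz; gamma 30–100 Hz split at 65 Hz. These are
  the conventional EEG definitions; published front-ends rarely state exact
  edges, so feature values are not bit-comparable across implementations.
* **Windowing** — 4 s windows, 2 s stride, 256 Hz sampling. Four seconds
  resolves the alpha band with $\ge 32$ cycles while remaining short against
  the hour-long pre-ictal period.
* **PSD** — a single-taper Hann periodogram per window: the simplest fully
  deterministic estimator. The DC bin is excluded from total power so
  electrode offset cannot dilute the fractions. An all-zero window has its
  fractions defined as 0.

Band fractions are scale-invariant (amplitude information lives entirely in
the peak-to-peak feature) and the three fractions sum to at most 1 — both are
property-tested.

## Labeling and evaluation

The four ictal states are labeled per window by its start time: the
pre-ictal period spans the hour before each onset, the post-ictal period the
hour after each offset (both configurable). Overlaps resolve by the
precedence ictal > pre-ictal > post-ictal > inter-ictal — when the tail of
one seizure meets the approach of the next, predicting the imminent seizure
wins.

* **Sensitivity** is alarm-based: a seizure counts as predicted iff at least
  one alarm window starts in its pre-ictal period. By default an alarm is any
  window classified pre-ictal; a consecutive-window debouncing parameter `m`
  is exposed (default 1).
* **Specificity** is window-based, over inter-ictal windows only — ictal and
  post-ictal windows are irrelevant to the wake-up decision. It equals the
  fraction of no-risk time the digital back-end stays idle.
* **Power model** — the back-end runs during pre-ictal time and inter-ictal
  false alarms: `duty = pre_frac + (1 - pre_frac)(1 - specificity)`;
  total power is the always-on analog front-end plus the duty-cycled digital
  engine. The hardware constants (180 nW analog, 166 K classifications/s,
  3.07 µW digital back-end) are configuration inputs with literature-scale
  defaults — this package models power, it does not measure it.
* **Training protocol** — classifiers are trained on pre-ictal vs inter-ictal
  windows only; ictal and post-ictal windows never enter training or
  specificity scoring. `training_iterations()` repeats training under
  different EM seeds and tabulates the per-seed specificity spread of the
  software baseline.

## What the synthetic generators emulate — and what they do not

Two generators make the pipeline self-contained:

* `simulate_feature_scenario()` works directly in feature space: windows laid
  over a generated timeline, pre-ictal windows drawn from one ground-truth
  4-D mixture, all others from another. The default truth
  (`default_feature_truth()`) raises amplitude and shifts power from alpha
  into gamma pre-ictally, with every dimension separating nearest cross-class
  cluster means by at least 4 standard deviations — a deliberately
  well-separated recording.
* `generate_eeg()` synthesizes the raw signal: unit-variance band-limited
  Gaussian noise per band (alpha, split gamma, and a 2–7 Hz residual), mixed
  with per-sample gains that track the active state's band-power profile and
  RMS amplitude, with 10 s crossfades at state boundaries. Closing the loop
  through `extract_features()` recovers the per-state target fractions within
  about ±0.05 — the small residual bias being band-edge leakage through the
  Butterworth skirts.
* `generate_timeline()` packs non-overlapping seizures with at least 2.5 h
  before each one, so hour-long pre/post periods never collide; the default
  scenario is a 24 h record with 4 seizures.

These generators reproduce the *statistical structure the classifier
assumes* — class-conditional Gaussian mixtures, state-dependent band power —
and nothing else. Real EEG has artifacts, non-stationarity within states,
heavy-tailed amplitude distributions, patient-to-patient variability and
pre-ictal signatures far subtler than 4σ. Passing tests on this synthetic
data therefore demonstrate that the pipeline is *correct*, not that the
method achieves any particular clinical performance; published specificities
near 70% on real recordings live in exactly the overlap region the default
scenario deliberately avoids. The `overlapping_feature_truth()` fixture used
in the Monte-Carlo tests (≈1.5σ separation) probes that regime.

## Problem sizes used by the tests

The shipped suite runs EM recovery at $n = 2000$ points, oracle-equivalence
sweeps at 1000 random instances, cascade identities at 1000 random
configurations, signal-level closed loops on 1–2 h records at 256 Hz, and
Monte-Carlo contracts at up to 100 runs on a few hundred windows; the
acceptance script evaluates the full 24 h, 4-seizure scenario (43,199
windows). These sizes were chosen so the whole suite runs comfortably on a
laptop while keeping every statistical check far from its decision boundary.

## Known limitations

* The behavioral model has no transient dynamics, noise, temperature
  dependence or layout parasitics; it is a steady-state functional model.
* The mismatch abstraction (three per-bump knobs) is not traceable to a
  specific process; its magnitudes are plausible defaults, not calibrated.
* EDF ingestion is not provided; signals enter as CSV or in-memory vectors.
* Single channel, binary classes, shared $K$; no model selection over $K$,
  no full-covariance mixtures, no Bayesian fitting.
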