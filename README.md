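# gmmwake

Software model of a nanopower **analog wake-up classifier** for epileptic
seizure prediction from single-channel EEG.

Wearable seizure-prediction devices cannot afford to keep an accurate digital
inference engine (µW–mW) running continuously. A wake-up architecture puts an
always-on, ~180 nW analog classifier in front: it watches four EEG features
and switches the digital back-end on only when a seizure appears imminent.
Its sensitivity must be total — every seizure predicted — while its
specificity sets how often the back-end wakes and therefore the total system
power. `gmmwake` is for engineers and researchers studying this architecture:
it implements the classifier, a behavioral model of its analog circuit
realization, the feature and evaluation pipeline around it, and synthetic
data generators so everything is testable without clinical recordings.

## The model

Each class *c* (pre-ictal vs inter-ictal) is a diagonal-covariance Gaussian
mixture over the 4-D feature vector *X* (peak-to-peak amplitude; alpha,
lower-gamma and upper-gamma energy fractions):

```
p(X | λ_c) = Σ_{i=1..K} w_i^c N(X | M_i^c, Σ_i^c),    y = argmax_c p(X | λ_c)
```

Diagonal covariance factorizes each component into a product of univariate
Gaussians — exactly what a chain of subthreshold **bump circuits** computes in
current mode: each bump contributes one sech²(≈ Gaussian) factor with mean,
width and height set by a control voltage pair (Vr, Vc) and a bias current
(I<sub>bias</sub>); cascaded bumps multiply, current mirrors sum clusters,
and a winner-take-all stage takes the argmax. The 2-class, 2-cluster, 4-D
classifier needs `2·C·K·N + C = 34` control parameters and, under the
package's fixed accounting convention, `8·C·K·N + C(K−1) + (C−1) = 131`
scalar operations per classification.

Mixtures are trained in software by expectation-maximization (`fit_em()`),
then mapped onto circuit parameters (`map_gmm_to_analog()`) through a
feature-to-voltage scaler and a numerically calibrated Vc↔width map.
Device mismatch is modeled as per-bump Gaussian perturbations for
Monte-Carlo robustness analysis.

## Worked example

Train and evaluate the wake-up classifier on a synthetic 24-hour record with
four seizures and well-separated pre-ictal vs inter-ictal feature
distributions:

```r
library(gmmwake)

tl      <- generate_timeline(duration = 86400, n_seizures = 4, seed = 1)
windows <- simulate_feature_scenario(tl, seed = 2) |> split_windows(seed = 3)
train   <- dplyr::filter(windows, .set == "train",
                         state %in% c("pre_ictal", "inter_ictal"))

clf <- fit_gmm_classifier(train, K = 2, seed = 4)
test <- dplyr::filter(windows, .set == "test")
evaluate_windows(clf, test, tl)
#> <eval_report>
#>   sensitivity: 100.0% (4 predicted / 0 missed)
#>   specificity: 100.00% (TN 14342 / FP 0)
#>   duty cycle: 17.0%, system power: 7.01e-07 W
```

All four synthetic seizures are predicted (≥ 1 alarm in each pre-ictal hour)
with no false alarms in inter-ictal time; the digital back-end would run 17%
of the time (the pre-ictal hours themselves), for about 0.7 µW total. Mapping
the same model onto the behavioral analog circuit and re-evaluating, then
stressing it with device mismatch:

```r
cfg <- map_gmm_to_analog(clf, scaler = feature_scaler(train))
evaluate_windows(clf, test, tl, mode = "analog", analog_cfg = cfg)
#> <eval_report>
#>   sensitivity: 100.0% (4 predicted / 0 missed)
#>   specificity: 100.00% (TN 14342 / FP 0)
#>   duty cycle: 17.0%, system power: 7.01e-07 W

monte_carlo_eval(cfg, mismatch_spec(n_runs = 20, seed = 5),
                 dplyr::slice_sample(test, n = 500))
#> <mc_result> 20 runs: mean specificity 100.00% sd 0.00%

accounting_report(architecture_spec(2, 2, 4))
#> <accounting_report> C=2 K=2 N=4
#>   parameters: 34, operations/classification: 131
#>   energy: 1.08e-12 J/classification, 8.28e-15 J/operation
```

On this deliberately separated scenario the analog model agrees with the
ideal classifier on every window and mismatch never flips a decision; the
vignette discusses the overlapping regime where it does. `autoplot()` methods
and `plot_alarm_raster()` visualize calibration curves, Monte-Carlo
histograms, the power/specificity trade-off and alarm rasters. A thin CLI
over the same functions lives at `inst/cli/gmmwake.R`
(`simulate`, `extract-features`, `train`, `map-analog`, `evaluate`,
`montecarlo`, `report`).

See `vignettes/wakeup-classifier.Rmd` for the full account of the model,
the behavioral circuit equations, every convention and default, and what
synthetic results do and do not demonstrate.

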