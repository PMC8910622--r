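# sleepstage

Automatic sleep staging from a single EEG channel.

Clinical sleep assessment scores polysomnography in 30-second epochs, each
labelled with one of the five AASM stages — W (wake), N1, N2, N3 (non-REM
depths) and REM. Manual scoring by an expert is slow and subjective;
`sleepstage` automates it from one EEG channel (typically Fpz-Cz sampled at
100 Hz, so an epoch is 3000 samples), which is what portable, wearable sleep
monitors can realistically record. The intended users are sleep researchers
and biomedical-signal engineers who want a transparent, fully reproducible
baseline pipeline rather than a black box.

## What it computes

Each epoch is summarized by **57 features**:

* **Time domain (T1–T15):** peak-to-peak amplitude, the first four central
  moments (mean, variance s², skewness, excess kurtosis), median, extrema,
  zero-crossing rate ZCR = N_Z/(N−1), normalized mean absolute first and
  lag-2 differences (δ̃ = δ/s, γ̃ = γ/s), and the Hjorth parameters
  (Activity = s², Mobility = s_Δx/s, Complexity = Mobility(Δx)/Mobility(x)).
* **Frequency domain (F1–F39):** a one-sided periodogram |DFT(x)/N|² over
  seven EEG rhythm bands (low-δ 0.5–2, high-δ 1.2–4, θ 4–8, α 8–13,
  low-β 13–20, high-β 20–30, γ 30–45 Hz) giving band powers E1–E9, the
  tabulated power ratios (e.g. F12 = E8/E1, F19 = E5/(E3+E4)), and
  power-weighted spectral moments (mean power frequency and frequency
  variance) per band.
* **Nonlinear (N1–N3):** Higuchi fractal dimension (slope of ln H(k) vs
  −ln k, k ≤ ⌊N/20⌋), the non-stationary index (SD of segment means,
  m = ⌊0.15N⌋ segments), and sample entropy
  SampEn(m=2, r=0.2·SD) = −ln(A/B) with Chebyshev distance.

On top of the features: embedded **feature screening** (seeded random-forest
impurity importances normalized to sum 1; keep weight > 0.02), four
**classifier configurations** (RBF SVM with C = 1.3, γ = 0.03 and z-score
scaling; a 2×18 backpropagation MLP with min–max scaling; an entropy
decision tree, depth 11 / leaf 11; a 100-tree random forest, depth 22 /
leaf 5), and the full **evaluation protocol** (stratified 20% hold-out,
stratified 5-fold CV, per-stage precision/recall/F1, confusion matrices,
Cohen's kappa, and the agreement rate between staging runs).

A minimal EDF/EDF+ reader/writer handles real recordings; a seeded
stage-conditioned synthetic EEG generator (α-dominant W, θ-dominant N1,
spindle-bearing N2, high-amplitude-δ N3, low-voltage mixed REM) makes the
whole pipeline testable offline. See the methods vignette
(`vignettes/sleep-staging-methods.Rmd`) for every convention and design
choice.

## Worked example

```r
library(sleepstage)

# 100 synthetic epochs per stage, fully seeded
ds <- generate_dataset(setNames(rep(100L, 5), sleep_stages()),
                       synthetic_recipe(), seed = 42)
features <- extract_features(ds)
features[1:4, c(1:5, 56:58)]
#> # A tibble: 4 × 8
#>   stage    T1       T2    T3    T4    N1    N2    N3
#>   <fct> <dbl>    <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 W      33.9 -0.00780  19.4  4.40  1.99  1.79  1.87
#> 2 W      27.7 -0.0142   18.2  4.27  2.00  1.63  1.90
#> 3 W      28.0  0.0292   16.8  4.10  1.99  1.48  1.88
#> 4 W      31.2 -0.00668  17.8  4.22  1.99  1.66  1.92

split <- stratified_split(features$stage, test_frac = 0.2, seed = 42)
fit   <- fit_stager(features[split$train, ], model_spec("RF", seed = 42))
pred  <- predict(fit, features[split$test, ])
report <- classification_report(
  confusion_matrix(features$stage[split$test], pred))
report
#> # A tibble: 5 × 6
#>   stage n_test n_correct precision recall    f1
#>   <fct>  <int>     <int>     <dbl>  <dbl> <dbl>
#> 1 W         20        20         1      1     1
#> 2 N1        20        20         1      1     1
#> 3 N2        20        20         1      1     1
#> 4 N3        20        20         1      1     1
#> 5 REM       20        20         1      1     1
glance(report)
#> # A tibble: 1 × 4
#>   accuracy macro_f1 kappa     n
#>      <dbl>    <dbl> <dbl> <int>
#> 1        1        1     1   100
```

Each row of the report is one stage: `n_test` held-out epochs, of which
`n_correct` were staged correctly; precision, recall and F1 are one-vs-rest.
The default synthetic recipe is deliberately well separated, so the random
forest stages it perfectly — real recordings are considerably harder, with
REM/N1 the dominant confusion. Screening then compresses the feature set:

```r
imp <- fit_importances(features[split$train, ], num_trees = 500, seed = 42)
sel <- select_by_threshold(imp, 0.02)   # features with weight > 0.02
fit_small <- fit_stager(features[split$train, ],
                        model_spec("RF", seed = 42), features = sel)
agreement_rate(pred, predict(fit_small, features[split$test, ]))
#> [1] 1
```

`autoplot(confusion_matrix(...))` draws the confusion heat map and
`plot_hypnogram(truth, pred)` the expert-vs-model stage traces.

The same workflow is scriptable from a shell via `inst/cli/sleepstage`
(`simulate`, `extract`, `select`, `train`, `evaluate`, `compare`), with all
parameters in a YAML config and every command byte-reproducible under a
fixed seed.

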