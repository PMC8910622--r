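---
title: "Methods: single-channel EEG sleep staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-channel EEG sleep staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepstage)
```

## The staging problem

Polysomnography scores sleep in 30-second epochs, each assigned one of the
five AASM stages: wake (W), three non-REM depths (N1, N2, N3) and REM.
`sleepstage` automates this scoring from a *single* EEG channel (typically
Fpz-Cz at 100 Hz, so one epoch is 3000 samples): each epoch is summarized by
57 numeric features, a tree-ensemble screening optionally reduces that set,
and one of four standard classifiers maps feature vectors to stages. The
package covers the full protocol — EDF input, preprocessing, feature
extraction, screening, model fitting and evaluation — plus a seeded synthetic
EEG generator so the entire pipeline is testable without any data download.

## Preprocessing

EEG is band-limited to 0.5–45 Hz with a linear-phase FIR band-pass before
feature extraction. The design is a 401-tap Hamming-window filter at 100 Hz
(`design_bandpass()`), applied forward–backward (`apply_filter()`) so the
output has zero phase: waveform timing relative to the expert labels is
preserved, at the cost of squaring the magnitude response (which only deepens
the stopband). Filtering precedes epoching, so edge transients sit at the
ends of the whole recording rather than at every epoch boundary. With these
defaults the single-pass response is flat to a fraction of a dB across
1–40 Hz and more than 20 dB down at 0.1 Hz and 49 Hz. No notch filtering or
artifact rejection is performed.

## The 57 features

**Time domain (T1–T15).** Peak-to-peak amplitude, mean, variance, SD,
median, skewness, excess kurtosis, maximum, minimum; the zero-crossing rate;
normalized mean absolute first and lag-2 differences; and the three Hjorth
parameters. All moments are *central* and divide by N (the excess-kurtosis
"−3" convention only makes sense for central moments, so centering is applied
throughout even where a formula is written without it). The zero-crossing
rate is computed after mean removal — crossings of the waveform's own
midline — counting strict sign changes (`x[i] * x[i+1] < 0`) over N−1
adjacent pairs; exact zeros do not count. "Amplitude" (T1) is defined as
max − min, the only reading consistent with max and min being listed
separately. Hjorth activity is the variance; mobility is SD(Δx)/SD(x);
complexity is Mobility(Δx)/Mobility(x) — the standard form, using the
iterated difference Δ(Δx) — while the *feature* T12 (ASDN) uses the lag-2
difference x(n+2)−x(n) as tabulated. For a pure sinusoid of frequency f at
sampling rate fs, mobility has the closed form 2·sin(π·f/fs), which the test
suite uses as an oracle.

**Frequency domain (F1–F39).** The spectrum is a one-sided periodogram,
`|DFT(x)[k]/nfft|²` with nfft = 3000 (the epoch length, rectangular window,
no padding); no one-sided doubling is applied, since every downstream
feature is a ratio or a power-weighted moment in which the convention
cancels. Seven rhythm bands are used, half-open `[lo, hi)`: low-δ 0.5–2,
high-δ 1.2–4 (the two δ bands deliberately overlap on 1.2–2 Hz), θ 4–8,
α 8–13, low-β 13–20, high-β 20–30, γ 30–45 Hz. E1 is the total power over
0.5–45 Hz (the filtered support), E2–E8 the band powers, and
E9 = E2+⋯+E8 (which double-counts the δ overlap, by construction). F1–F6
are band powers and sums, F7–F25 the tabulated power ratios; a zero
denominator yields a flagged 0 rather than an error. F26–F39 are spectral
moments per band: the mean power frequency MPF_S = Σ f·P(f) / Σ P(f) and the
frequency variance FV_S = Σ (f − MPF_S)²·P(f) / Σ P(f) over a frequency set
S — the full band, the four narrow bands, β combined as 13–30 Hz, and γ.
These are the standard first and second power-weighted spectral moments;
that definition is a documented package convention, stated here because
"MPF"/"FV" are used ambiguously in the literature.

**Nonlinear (N1–N3).** The Higuchi fractal dimension builds normalized
curve lengths H(k) at lags k = 1..⌊N/20⌋ (averaged over the k offsets) and
takes the least-squares slope of ln H(k) against −ln k via the closed-form
ratio estimator, which is bit-stable across platforms; a straight line gives
1.00 and white noise approaches 2. The non-stationary index splits the epoch
into m = ⌊0.15·N⌋ contiguous segments, as equal as possible (the first
N mod m segments one sample longer), and reports the population SD of the
segment means. Sample entropy is −ln(A/B) with Chebyshev distance, tolerance
r = 0.2·SD(epoch), template length m = 2, self-matches excluded; both counts
run over the N−m template starts that admit an (m+1)-length extension (the
Richman–Moorman convention used by every major implementation). When no
template pair matches, the value is undefined and flagged rather than
regularized — adding an ε would silently bias exactly the epochs where the
statistic carries no information. The two O(N²)/O(N·k) inner loops are
compiled (Rcpp); plain-R brute-force transcriptions of the definitions serve
as oracles in the tests.

Degenerate inputs follow one rule everywhere: a feature whose definition
requires positive variance (or a nonzero denominator) returns 0 — flagged
via an attribute — so feature tables stay finite for the classifiers.

## Screening and classifiers

Embedded screening fits a seeded random forest (Gini impurity, impurity-
decrease importances normalized to sum 1) and keeps features whose weight is
*strictly* greater than 0.02, in descending weight order. The strict
inequality matters: on the bundled reference weights, kurtosis sits at
0.0201 and is kept, giving the reference 11-feature set. By default the
importances are fitted on the training split only, to avoid selection
leakage into the held-out evaluation; `use_all_data` flips this for
comparison with protocols that screened on the pooled data.

The four classifier configurations (`model_spec()`):

| kind | configuration | scaling |
|------|---------------|---------|
| SVM  | RBF kernel, C = 1.3, γ = 0.03, one-vs-rest | z-score |
| BPNN | 2 hidden layers × 18 sigmoid units, softmax out, SGD lr 0.1 | min–max to [0, 1] |
| DT   | entropy criterion, max depth 11, min leaf 11 | none |
| RF   | 100 Gini trees, max depth 22, min leaf 5 | none |

Design notes on the genuinely open choices:

* **SVM kernel.** A γ hyperparameter only exists for the RBF kernel, so the
  default is RBF with the stated (C, γ); a linear kernel remains available
  via `model_spec("SVM", kernel = "linear")`. Multi-class handling is
  one-vs-rest (five binary machines, arg-max over decision values).
* **BPNN.** Two hidden layers of 18 is the configuration the defaults
  target (a single layer of 20 is one override away). No R package on hand
  fits multi-hidden-layer perceptrons, so the package carries a compact
  backpropagation implementation: mini-batch SGD (batch 32) with momentum
  0.9, learning rate 0.1, at most 500 epochs, early stopping on a 10%
  validation split with patience 25 — a stopping rule had to be fixed, and
  validation-loss early stopping is the standard one.
* **DT.** C4.5's gain-ratio splitting is approximated by entropy-criterion
  CART (`rpart`) with the stated depth/leaf constraints; exact C4.5 is out
  of scope and the approximation is noted here deliberately.
* Scalers are fitted on training data only and stored inside the model, so
  prediction replays the training transform; features are matched by name,
  never by position.

## Evaluation protocol

`stratified_split()` holds out 20% with largest-remainder per-class
rounding and a ceiling total, so the balanced 9696-epoch corpus yields
exactly 1940 test epochs. `kfold_cv()` runs stratified 5-fold
cross-validation on the training portion. `classification_report()` gives
per-stage one-vs-rest precision, recall and F1 = TP/(TP + (FN+FP)/2)
(identically the harmonic mean), pooled accuracy = trace/total, and
`cohen_kappa()` the chance-corrected agreement. `agreement_rate()` is the
fraction of epochs on which two staging runs coincide — used to compare
full-feature and screened-feature staging. Reports are rounded for display
to 4 decimals (metrics) and 2 (accuracy percentages). Per-stage "accuracy"
in the comparison grid of `run_compare()` is per-stage *recall*, which is
what per-stage percentages in staging papers conventionally are.

## The synthetic generator

`generate_epoch()` builds an epoch as a weighted sum of band-limited
Gaussian noise components — white noise passed through the same 401-tap FIR
band designs as the preprocessing module, applied via their DFT-domain
transfer functions — plus a broadband noise floor, scaled per stage, with
N2 additionally carrying 12–14 Hz spindle bursts (Gaussian envelope,
Poisson rate 2/epoch) and biphasic K-complex transients (rate 1/epoch).
The default gains emulate textbook stage physiology: α-dominant W,
θ-dominant N1, mixed δ/θ N2 with spindles, high-amplitude δ N3 (≈2.5× the
W amplitude scale), and low-voltage mixed-frequency REM whose β/γ admixture
keeps it separable from N1. Reproducibility is per-epoch: every epoch's
seed derives deterministically from the master seed.

What the generator does *not* emulate — and hence what passing tests do and
do not show: real EEG has artifacts, non-stationary stage transitions,
inter-subject variability, and a REM/N1 boundary that experts themselves
find ambiguous. The default recipe is intentionally well-separated so that
classifier and pipeline tests are stable; `synthetic_recipe(hard = TRUE)`
narrows the REM/N1 gap for qualitative demonstrations of the real
confusability. High accuracy on the synthetic benchmark therefore validates
the *pipeline machinery* (features carry the stage signal; models recover
it; seeds reproduce it), not clinical-grade performance: real recordings
are substantially harder, and the REM/N1 boundary dominates the errors.

## Problem sizes and numerical choices

The packaged benchmark sizes are chosen to keep a full check fast on one
CPU while leaving the statistics meaningful: the end-to-end synthetic
benchmark uses 200 epochs per stage (1000 epochs, 57 features, a 20%
held-out test set; chance accuracy 20%), oracle-equivalence batteries use
100 random epochs of 250–500 samples, and Monte-Carlo closed-form checks
average 20 seeds. The balanced-corpus split check uses the full 9696-epoch
label layout, where only labels (not signals) are needed. Tolerances in the
tests are stated per check: exact (≤1e−12) for pure arithmetic and oracle
equivalence of discrete counts, 1e−9 relative for spectral sums against
direct DFT oracles, and distributional slack (e.g. FD of white noise
2.0 ± 0.1 over 20 seeds) where the quantity itself is stochastic.

## Known limitations

* Single channel, single epoch: no EOG/EMG fusion, no hypnogram smoothing
  (e.g. HMM post-processing), no per-subject cross-validation — epochs are
  pooled, as in the protocol this package follows.
* The overlapping δ bands and the E9 double-count are kept as specified for
  fidelity; they are conventions, not bugs, but mean E9 is not a partition
  of E1.
* The EDF codec is minimal by design: 16-bit EDF/EDF+ signals and
  annotation channels; 24-bit BDF and discontinuous (EDF+D) files are
  rejected with a clear error.
* Sample entropy on a constant or near-constant epoch is undefined; such
  epochs surface as flagged zeros in the feature table and deserve
  attention upstream if they occur in real data.
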