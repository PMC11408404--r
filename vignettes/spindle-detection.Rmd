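---
title: "Detecting sleep spindles in polysomnographic EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sleep spindles in polysomnographic EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindler)
```

## The problem

Sleep spindles are transient sigma-band (≈11–16 Hz) EEG oscillations with a
fusiform envelope, lasting roughly 0.5–3 s, generated by thalamocortical
circuits during NREM stage-2 sleep. Counting them by eye across a full
night of six-channel polysomnography is tedious and rater-dependent.
`spindler` frames detection as supervised classification of 10-s frames:
every 30-s scoring epoch is cut into three frames per channel, each frame
is reduced to twelve spectral and higher-order features, and a classifier
decides whether a spindle is present. This vignette documents the model,
its tunable parameters, the synthetic benchmark, and the numerical and
design choices a user should know about.

## Preprocessing

Missing samples are replaced by the channel mean (`impute_missing`), then
each channel of each recording is min–max normalized to [0, 1]
(`minmax_normalize`). Two choices here were genuinely open:

* **Normalization scope.** Constants are computed per channel per
  *recording*, not per frame. Per-frame scaling would erase exactly the
  between-frame amplitude contrast that distinguishes a spindle-bearing
  frame from background, so the pipeline deliberately preserves it. All
  features are additionally computed on mean-removed signals, making them
  invariant to a constant offset; the normalization therefore only sets an
  amplitude scale per recording.
* **Frame geometry.** Frames are half-open intervals `[start, start+10 s)`
  with 0-based sample indexing; a trailing partial epoch is discarded
  rather than padded, so every frame has exactly `10 × fs` samples.

The stratified train/test split (default 70/30) operates at the segment
level, matching the frame-level confusion matrix that evaluation uses. For
real multi-night data a recording-level grouping would be the safer default
against leakage of recording-specific background statistics; the
segment-level default mirrors the frame-centric protocol, and all features
are per-frame quantities.

## The four feature families

**Power spectral density.** The PSD is defined as the Fourier transform of
the signal autocorrelation. The package carries three estimators that are
kept deliberately redundant: the periodogram and an autocorrelation-route
transform, which agree to machine precision (Wiener–Khinchin) and are used
as mutual cross-checks in the test suite, and Welch averaging (2-s Hann
windows, 50% overlap) as the production estimator, trading frequency
resolution (0.5 Hz at the default window) for variance reduction. Band
powers are rectangular integrals over half-open bands; the canonical EEG
bands plus relative sigma power and the 9–18 Hz spectral peak give seven
scalars. Both exact routes conserve variance under rectangular integration
(Parseval), which the tests assert within 1%.

**Continuous wavelet transform.** The analytic Morlet wavelet with center
frequency ω₀ = 6 is evaluated on 32 log-spaced scales whose equivalent
frequencies span 2–30 Hz — wide enough to normalize sigma-scale energy
against the whole background, fine enough (≈9% spacing) to land within one
scale step of any sigma carrier. The sigma-scale mean and maximum
coefficient magnitude and the sigma share of total scalogram energy give
three scalars. The transform uses the `1/√α` prefactor of the standard CWT
definition; kernels are cached per (length, rate, scale-grid), which is
what makes featurizing thousands of frames cheap.

**Gaussianity score.** Background EEG within a 10-s frame is close to
Gaussian; a high-amplitude burst stretches the tails of the amplitude
distribution. The score compares the sorted standardized sample against
normal reference quantiles at Blom plotting positions
`(j − 0.375)/(N + 0.25)` — the conventional choice for normal probability
plots — and returns `1 − Σ(qⱼ−pⱼ)²/Σ(qⱼ−q̄)²`. It is exactly 1 when the
sample quantiles coincide with the reference and strictly below otherwise;
despite the "non-Gaussianity" framing common for this family of scores,
larger values mean *more* Gaussian, and the classifier is free to use
either direction. A zero-variance frame has no defined standardization and
raises an error, which the feature assembler reports with the segment id.

**Bispectrum score.** The third-order spectrum retains Fourier phase
information that the PSD discards. The direct estimator partitions the
frame into 8 Hann-windowed blocks (160 samples at 128 Hz, above the
64-sample floor), and averages `X(ω)² · conj(X(2ω))` across blocks; the
diagonal slice is reported up to `fs/4` so that `2ω` stays on the grid.
The score integrates the slice over sigma (11–16 Hz) against a broadband
denominator (0.5–30 Hz); both bands are configurable. Note that the
*diagonal* slice responds to quadratically phase-coupled triples of the
form (f, f, 2f): a coupled triple with two distinct base frequencies lives
off the diagonal and is invisible here, which the tests respect by probing
with an (f, f, 2f) construction.

## Classifiers and feature selection

Feature selection is a one-way ANOVA-F filter: for each feature the
between-class over within-class mean-square ratio, computed on training
rows only, with the top k = 10 of 12 features retained by default. A
filter (rather than a wrapper) keeps selection independent of the
classifier and cheap.

Five classifiers sit behind the single fitting surface
`spindle_classifier()`: KNN (k = 5, Euclidean, distance ties broken
deterministically toward lower row index), RBF SVM (C = 1, γ = 1/d on
standardized features, score = logistic of the decision value), a CART
decision tree (Gini, grown to purity), Gaussian naive Bayes, and extremely
randomized trees (100 trees). No hyperparameter search is performed — the
defaults are the conventional ones, every value is exposed, and training is
deterministic given the seed, which we judged more valuable for a
measurement instrument than a few tenths of a point of accuracy.
Standardization statistics are learned from training rows only and stored
in the model, so prediction never touches test-set statistics.

## Evaluation

Frame-level confusion counts give accuracy, sensitivity, specificity,
precision, F1 and MCC; any metric with a zero denominator is defined as 0
and flagged `undefined` rather than NaN. The ROC sweeps the sorted unique
scores (descending, with an `Inf` sentinel) and integrates trapezoidally.
Spindle *counts* use the frame-union rule — a frame counts once if any
channel is positive — because the 10-s frame is the counting unit;
per-recording counts from ground truth and from the detector are compared
with a two-way consistency intraclass correlation, reported in both
single-measures `(MSR−MSE)/(MSR+MSE)` and average-measures
`(MSR−MSE)/MSR` forms (k = 2 raters). The consistency family was chosen
because the comparison asks whether two scorers *rank and scale* recordings
together, not whether they agree absolutely; both forms are reported so
either convention can be read off.

## The synthetic benchmark

Real overnight PSG with expert spindle annotations cannot ship with a
package, so the simulator is a first-class module. It emulates the
features of NREM EEG that matter to a sigma-band detector:

* background: Gaussian 1/f^α noise (α = 1, RMS 10 µV) — the canonical
  broadband EEG spectrum;
* spindles: Hann-enveloped sinusoids, 0.5–3 s, placed by a homogeneous
  Poisson process (3 events/min/channel) with same-channel overlap
  rejection; slow spindles (12–13 Hz) on frontal channels, fast
  (14–15 Hz) elsewhere, peak amplitude twice the background RMS;
* six referential channels (F4-M1, C4-M1, O2-M1, F3-M2, C3-M2, O1-M2) at
  128 Hz — a typical PSG montage and storage rate.

It does **not** emulate sleep-stage architecture, K-complexes, arousals,
EMG/electrode artifacts, or inter-subject variability in spindle
morphology. Passing the benchmark therefore shows that the feature
families separate fusiform sigma bursts from 1/f background at a 2:1
amplitude ratio and that the pipeline is leak-free and reproducible — it
does not certify clinical-grade performance on real recordings.

The default benchmark is 12 recordings × 20 min × 6 channels (8640 frames,
split 6048/2592), sized so a full run takes well under a minute on one
core; a frame label requires ≥0.25 s of event overlap. At 3 events/min on
six channels the union-rule counts sit near the frames-per-recording
ceiling, so the between-recording count variance the ICC works with is
small; the ICC nevertheless resolves the agreement (average ≈ 0.92 with
the default seeds).

```r
report <- run_pipeline(run_config())
report
#> Spindle pipeline report (KNN, 8640 segments: 6048 train / 2592 test)
#>   accuracy 0.9765  sensitivity 0.9496  specificity 1.0000  AUC 0.9807
#>   counts ICC: single 0.8592, average 0.9242
```

## Numerical choices and degenerate inputs

* Min–max of a constant vector is defined as all zeros (0/0 → 0).
* Filter score of a feature with zero between- and within-class variation
  is 0; perfect separation with zero within-class variance scores `Inf`,
  which ranks first, as it should.
* The EDF writer pads each channel's physical range by 1% (unit pad for a
  constant channel) so the 16-bit linear map is never degenerate;
  round-trip error is bounded by one quantization step.
* `select_top_k` and KNN break ties toward the lower index so that every
  run of the pipeline is bit-reproducible; all randomness flows through
  three named seeds (`sim`, `split`, `model`).
* A spindle-free simulation leaves one class empty; the pipeline stops at
  the split stage with a stage-named error instead of producing a
  meaningless report.

## Limitations

Frame-level scoring cannot localize a spindle within its 10-s frame or
split two spindles inside one frame; density is bounded by 6 frames/min.
The 70/30 segment-level split mirrors a frame-centric protocol but is
optimistic for cross-recording generalization. The simulator's spindle
morphology is stylized (pure Hann-windowed sinusoids), and real scalp EEG
adds artifacts and non-stationarity the benchmark does not model.
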