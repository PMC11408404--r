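# spindler

Automatic detection of **sleep spindles** in multi-channel polysomnographic
EEG. Sleep spindles are sigma-band (≈11–16 Hz) oscillatory bursts with a
fusiform (waxing–waning) envelope lasting ≈0.5–3 s — the hallmark
grapho-element of NREM stage-2 sleep and a window onto thalamocortical
function. Visual spindle scoring of a full night is slow and
rater-dependent; `spindler` implements a supervised detector that scores
every 10-s frame of each EEG channel for spindle presence, for sleep
researchers and PSG technologists who need reproducible counts and
densities.

## Method

Each 30-s PSG epoch is cut into three 10-s frames per channel. After mean
imputation of missing samples and per-channel min–max normalization, every
frame is summarized by twelve features from four families:

- **PSD** — the power spectral density Φ(Ω), the Fourier transform of the
  signal's autocorrelation A(ξ) (estimated by Welch averaging): band powers
  in δ (0.5–4), θ (4–8), α (8–11), σ (11–16) and β (16–30) Hz, the relative
  sigma power, and the spectral peak in 9–18 Hz.
- **CWT** — continuous Morlet wavelet coefficients
  C(b, α) = α^(−1/2) ∫ f(t) φ((t−b)/α) dt: mean and maximum |C| over
  sigma-equivalent scales and the sigma share of scalogram energy.
- **NGS** — a normal-probability-plot score
  NGS = 1 − Σⱼ(qⱼ−pⱼ)² / Σⱼ(qⱼ−q̄)², where q are the sorted standardized
  frame samples and p the matching normal quantiles; it equals 1 for
  Gaussian-ordered data and drops when a high-amplitude burst deforms the
  amplitude distribution.
- **BGS** — the bispectrum diagonal slice P(ω) = |B(ω, ω)|, which retains
  Fourier phase information, integrated as a band ratio
  BGS = ∫σ P(ω) dω / ∫broadband P(ω) dω.

An ANOVA-F filter ranks the features; the top k (default 10) feed one of
five classifiers (KNN, SVM, decision tree, naive Bayes, extremely
randomized trees) trained on a stratified 70 % split and evaluated on the
remaining 30 %: frame-level confusion matrix, accuracy / sensitivity /
specificity / precision / F1 / MCC, ROC–AUC, and intraclass correlation
between ground-truth and predicted per-recording spindle counts.

A built-in simulator generates colored-noise background EEG with
ground-truth spindle annotations (slow 12–13 Hz spindles on frontal
channels, fast 14–15 Hz centroparietally), so the whole pipeline is
testable without clinical recordings. EDF I/O and an annotation CSV format
connect the package to real PSG exports.

## Worked example

```r
library(spindler)

## simulate a recording, extract features for one channel frame
sim  <- simulate_recording(sim_config(seed = 1, duration_s = 300))
segs <- segment_recording(normalize_recording(sim$recording))
round(assemble_features(segs$values[2, ], segs$fs), 4)
#> bp_delta  bp_theta  bp_alpha  bp_sigma  bp_beta  rel_sigma  peak_hz
#>   0.0027    0.0011    0.0003    0.0006   0.0008      0.102     13.5
#> cwt_sigma_mean  cwt_sigma_max  cwt_sigma_ratio     ngs     bgs
#>         0.0747         0.1849           0.0600  0.9958  0.0288

## full pipeline on the default 12-recording benchmark
report <- run_pipeline(run_config())
report
#> Spindle pipeline report (KNN, 8640 segments: 6048 train / 2592 test)
#>   accuracy 0.9765  sensitivity 0.9496  specificity 1.0000  AUC 0.9807
#>   counts ICC: single 0.8592, average 0.9242
```

The frame above contains a 13.5 Hz spindle: its spectral peak sits in the
sigma band and its relative sigma power (0.102) is elevated over the
1/f background. On the benchmark, the KNN detector recovers ~95 % of
spindle-positive frames with no false positives, and its per-recording
counts agree with ground truth (average-measures ICC 0.92).

The confusion-matrix helpers work directly from printed counts:

```r
metrics(confusion_counts(tp = 12541, fp = 1014, tn = 13972, fn = 492))
#> accuracy 0.9463  sensitivity 0.9622  specificity 0.9323
#> precision 0.9252  F1 0.9434  MCC 0.8929
```

## Command line

A thin CLI wraps the package functions:

```sh
Rscript inst/cli/spindler.R simulate --out rec.edf --events events.csv
Rscript inst/cli/spindler.R extract --edf rec.edf --events events.csv --out features.csv
Rscript inst/cli/spindler.R run --out-dir results/
```

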