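---
title: "Locating the onset of a relaxed state in alpha-band EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating the onset of a relaxed state in alpha-band EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A person entering a relaxed state shows increased alpha-band (8–13 Hz)
activity over the occipital cortex, but the moment at which the state sets
in during a stimulation session is not directly observable. `relaxera`
frames onset detection as a model-selection problem: among alpha
sub-bands, time-period groups of the stimulus, and sliding windows within
them, find the cell where a relaxed-versus-sad classifier generalizes
best. If the discriminating signal only exists late in the stimulus, the
accuracy landscape localizes it — that is the Effective Relax Acquisition
(ERA) search.

```{r setup}
library(relaxera)
```

## Data model and labeling

The expected container mirrors the DEAP preprocessed layout: per subject a
`data[trials × channels × samples]` array at 128 Hz with 63-s trials (3-s
neutral baseline + 60-s stimulus) and `labels[trials × 4]` holding 1–9
valence/arousal ratings (dominance and liking are ignored). Ratings map to
emotion quadrants by binary splits of both axes — low 1–4, high 6–9,
anything in the open gap (4, 6) excluded. The default contrast is LAHV
(low arousal, high valence: relaxed) versus LALV (low arousal, low
valence: sad), the pairing for which relaxed-state classification has
proven most separable; other pairings are configurable. Four DEAP
subjects (S13, S20–S22) are conventionally excluded as non-responders;
the exclusion list is a configuration key, not a hard-coded rule.

## Transformation

Each trial is Butterworth band-pass filtered to 8–13 Hz and restricted to
O1/O2. The filter order (4) and zero-phase application (forward–backward)
are package choices: the phase handling matters because a causal filter
would delay exactly the onset timing the search is meant to localize.
Filtering covers the full 63 s including baseline, before transformation.

The real Morlet wavelet `cos(5t)·exp(−t²/2)` is correlated with the signal
at integer scales 8–13 (L2 normalization, zero-padded edges). Its center
frequency, 0.8125 cycles per sampling period, is the value under which the
pseudo-frequency map `f = f_c/(s·Δ)` reproduces the sub-band
correspondence used throughout: scale 8 ↔ 13 Hz and scale 13 ↔ 8 Hz at
128 Hz. High Alpha (11–13 Hz) is scales 8–10, Low Alpha (8–10 Hz) scales
11–13, and both are row-slices of the one six-scale decomposition, so the
transform is computed once per trial and sliced per sub-band.

The stimulus span is divided into 4 or 6 equal contiguous period groups
(half-open sample intervals, 0-based; the 4-group boundaries are 384,
2304, 4224, 6144, 8064). A non-divisible span is a configuration error
rather than a silent truncation. Windows of length `wl_s` shifted by
`osw_s` are applied *within* each group — they never straddle group
boundaries, because the search treats groups as independent candidates for
where the state emerges. The window count follows the standard convention
`floor((N − wl·fs)/(osw·fs)) + 1`, validated in the tests against an
exhaustive enumeration of start offsets (a 60-s span with WL = 3 s,
OSW = 2 s gives 29 windows). Published tabulations of such counts are not
mutually consistent under any single start/end convention; the enumeration
convention is used and the discrepancy documented rather than resolved.

## Features

Thirteen features are computed per window, scale and channel, on the raw
real coefficients (the wavelet is real, so no magnitude step is needed).
Two definitional choices deserve note because the naming conventions in
the literature are looser than the formulas:

* **Mean absolute** is implemented as `|mean(w)|` — absolute value outside
  the sum — with `mean(|w|)` available behind
  `feature_options(mean_abs_variant = "mean_of_abs")`.
* **Amplitude maximum** is the plain `max(w)`, not `max(|w|)`; the
  absolute variant sits behind `amplitude_abs = TRUE`.
* **Differential entropy** is `½·ln(2πσ²)` with the sample variance; the
  Gaussian closed form `½·ln(2πeσ²)` is available via `de_standard =
  TRUE`. At σ² = 1/(2π) the default form is exactly 0, which the tests
  use as a spot check.
* **Wavelet entropy** treats the normalized squared coefficients within
  the window at one scale as an energy distribution over time,
  `−Σ p·log₂ p` with `p_i = w_i²/Σw²`, keeping the feature per-scale so
  the 13 × scales × channels column layout holds.
* **Shannon entropy** bins window values into 10 equal-width bins over
  `[min, max]` (log base 2) — a deterministic, common default; the bin
  count is configurable.
* **Hjorth parameters** use first differences as derivative
  approximations; a sampled sine then has mobility `2·sin(πf/fs)`
  exactly, which anchors the oracle tests.
* **Higuchi fractal dimension** uses the standard curve-length
  construction with `k_max = 8` (a common EEG setting) and a least-squares
  fit of `ln l(k)` on `ln(1/k)`; ramps score ≈ 1 and white noise ≈ 2.
* **Zero crossings** count strict sign alternations; literal zero samples
  neither terminate nor start a crossing.

Degenerate windows (zero variance, all-zero energy) raise errors rather
than silently producing zeros: a constant EEG window indicates a broken
recording, not a value of zero complexity.

## Reduction

Feature columns are z-scored before the covariance eigendecomposition —
the features span orders of magnitude (band power vs a fractal dimension),
so raw covariance would reduce PCA to a band-power ranking; a flag
disables scaling. Eigenvalues are sorted descending and clipped at zero;
eigenvector signs follow a deterministic convention (largest-magnitude
loading positive, ties to the lower index) so feature rankings are
reproducible. Component count selection offers three strategies: smallest
k reaching a cumulative-variance threshold (default 0.95), that k plus the
largest marginal gain among qualifying components (the reasoning that
prefers six components when the fifth-to-sixth increment dominates), or a
fixed k (default 6, the pipeline's default operating point). Feature
significance is the maximum absolute loading across the retained
components; an eigenvalue-weighted sum-of-squares score is available as an
alternative, since magnitude-based ranking does not prescribe an
aggregation across components. PCA can be fitted pooled across subjects
(default) or per subject.

## The search and its statistics

Each (sub-band, period group) cell is scored by one stratified K-fold
cross-validation (K = 5) over the cell's pooled window rows, with the full
reduction pipeline refitted inside every training fold so no
standardization or PCA statistics leak into test folds. Folds are
assigned at the *trial* level by default — all windows of a trial stay
together — because overlapping windows of one trial share samples and
row-level splitting would leak; a row-level mode exists for comparability
with pooled-row protocols. The cell's accuracy is the pooled held-out
accuracy over all its rows (the same quantity a per-cell accuracy table
over augmented window rows reports), and the per-window objective is the
held-out squared 0/1 error restricted to that window's rows — for binary
labels the squared error is the error count, so minimizing it is exactly
maximizing accuracy.

The best cell maximizes grid accuracy (ties resolve High Alpha before Low
Alpha before full alpha, then the earlier group); the onset window is the
objective argmin within that cell, searched from window 2 because the
first window of each group serves as the baseline frame (ties resolve to
the earliest window). Scoring cells on pooled rows rather than on a
per-window maximum also keeps the null calibration honest: a maximum over
dozens of 40-row windows would sit far above 50% on label-free data by
selection bias alone, whereas the pooled accuracy stays near chance, which
the tests verify over 20 null seeds.

Classifiers are off-the-shelf behind one fit/predict contract: KNN (k = 5,
Euclidean), RBF-kernel SVM (C = 1), and gradient-boosted trees (100 trees,
depth 3, single-thread for determinism). The defaults are conventional
values, exposed in the configuration. KNN is the default, being the
classifier of record for this kind of overlapping-window feature data.

## The synthetic test bed

`generate_dataset()` emulates the DEAP shape with a controllable contrast:
pink (1/f) background noise — chosen over white so the filter and CWT
stages face a realistic spectrum — plus Low Alpha (8–10 Hz) and High Alpha
(11–13 Hz) oscillators with per-trial random frequency and phase, slow
±20% amplitude jitter, and configurable inter-channel correlation
(default 0.8). Both classes share base amplitudes (10 µV, with 10 µV
noise) until the class onset, after which class-specific amplitudes apply
through a 1-s linear ramp. The default scenario gives the relaxed class a
2× High Alpha boost from 45 s after stimulus onset — confining the
discriminating signal to the last 15 s, i.e. the 4th of 4 period groups
(and the last 1.5 of 6 groups) — with 20 trials per class; these defaults
are the study conditions for the recovery tests.

What passing recovery tests show — and what they do not: the generator has
the band structure, onset step and noise color of relaxed-state EEG, but
no eye blinks, no non-stationary noise regimes, no inter-subject
variability and no volume-conduction structure beyond one correlation
knob. Recovery of the injected (sub-band, period) under these conditions
demonstrates the search's statistical machinery, not performance on
clinical recordings.

## Problem sizes and determinism

The bundled tests run the recovery check at 20 trials per class over 20
seeds with WL = 3 s and OSW = 2 s (7 windows per 15-s group; 280 rows per
cell), for the 4-group and 6-group layouts plus 20 null seeds — the scale
at which one replicate takes a few seconds, chosen so the whole suite
stays comfortably interactive. Denser windowing (OSW = 0.5 s, 115 windows
over a 60-s span) is the default for real analyses. All randomness —
generator streams (derived per trial from one master seed), fold
assignment, classifier tie-breaks — is seeded; KNN and SVM runs are
bit-reproducible, and the boosted-tree path is reproducible in its
single-threaded configuration.

## Known limitations

* The container is an R serialization of the DEAP array layout; reading
  DEAP's original Python pickles or MATLAB files requires a one-time
  external conversion.
* Only binary quadrant contrasts are supported, not 4-quadrant
  classification.
* The per-window onset estimate has the resolution of the window step and
  inherits the accuracy plateau of the cell; with strong effects several
  windows tie at zero error and the earliest is reported.
* Features are computed on real-valued Morlet coefficients; complex
  wavelets (instantaneous amplitude/phase) are out of scope.
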