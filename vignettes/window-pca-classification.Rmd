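---
title: "Window PCA for signal classification: model, choices, limits"
author: "dpcaw"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window PCA for signal classification: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpcaw)
```

## The model

Long physiological recordings such as EEG are one-dimensional sampled
signals $y(n)$, $n = 1, \dots, N$, in which the events of interest
(seizure activity, interictal discharges) express themselves both in the
*correlation structure* within short stretches of signal and in the
*power* of those stretches. The package turns this into a supervised
classification problem over windows:

1. **Non-overlapping window embedding.** A signal is partitioned into
   $m = \lfloor N / l \rfloor$ disjoint windows of length $l$; window $w$
   holds samples $(w-1)l + 1, \dots, wl$ and becomes one row of a data
   matrix $D^y \in \mathbb{R}^{m \times l}$. This is dynamic PCA
   (singular spectrum analysis) with the Hankel trajectory matrix —
   whose $N - l + 1$ rows are shifted copies of each other, hence highly
   autocorrelated — replaced by disjoint blocks. PCA's inferential
   behaviour relies on weakly dependent observations, so the disjoint
   embedding both removes the redundancy and shrinks the computation:
   at $N = 4096$, $l = 512$ the trajectory matrix has 3585 rows, the
   disjoint one 8. Rows from all training signals of all $g$ classes
   are stacked (and row-shuffled with a seed, so consecutive windows of
   one signal are not adjacent) into the training matrix $D$.
2. **PCA on the window covariance.** The $l \times l$ sample covariance
   of the mean-centered training rows is eigendecomposed,
   $C = V \Lambda V^\top$, giving loading vectors $V_1, \dots, V_l$
   ordered by decreasing eigenvalue. Any window $Y(w)$ projects to
   scores $\hat y_v(w) = \langle Y(w) - \bar{D},\, V_v \rangle$.
3. **Sparse features.** Two per-window descriptors, both 3-dimensional
   by default so the feature cloud can be inspected directly:
   * **FFPC** — the first few PC scores,
     $(\hat y_1, \hat y_2, \hat y_3)$: a similarity measure against the
     dominant correlation patterns of the training data.
   * **PCPEM** — the first two scores plus the PC-space energy
     $E(w) = \sum_{v=1}^{t} \hat y_v(w)^2$: the energy coordinate
     captures amplitude differences that score directions miss. With
     $t = l$ the energy is exactly the squared centered window norm
     (Parseval); $t = \lfloor l/2 \rfloor$ is the default, which is
     sufficient in practice because the trailing PCs carry noise.
4. **1-NN with stratified k-fold CV.** A one-nearest-neighbour rule in
   Euclidean distance, evaluated by stratified 10-fold cross-validation
   over windows, with the PCA model refitted on the training folds of
   every split. Accuracy is the pooled fraction of correctly labeled
   test windows; the report also carries per-fold values, mean $\pm$ sd,
   and a secondary per-segment majority-vote accuracy.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `windowLength` (`l`) | 512 (short segments); up to 1280 for long records | samples | long enough to resolve the rhythms of interest (~3 s at 173.61 Hz); larger `l` raises per-window information but costs training windows |
| `nComponents` (FFPC) | 3 | — | keeps the feature cloud plottable; extra dimensions have not improved window accuracy for signals of this kind |
| `nPcs` (PCPEM) | 2 | — | third coordinate is replaced by the energy |
| `truncation` | `floor(l / 2)` | scores | trailing PCs are noise-dominated; half the basis retains the discriminative energy |
| `k` | 10 | folds | standard bias/variance compromise for a few hundred to a few thousand windows |
| `standardize` | `TRUE` for PCPEM, `FALSE` otherwise | — | the energy coordinate is on a squared-amplitude scale and would otherwise dominate Euclidean 1-NN distance; statistics come from training folds only |

## Design choices that were genuinely open

* **Centering.** PCA of a covariance matrix implies mean-centering; the
  training mean is stored and subtracted from every projected window.
  There is no per-window centering and no correlation-matrix option:
  all `l` lagged variables share units, so variance scaling would only
  discard power information.
* **Eigenvector conventions.** Eigen-solvers return arbitrary signs, so
  each loading is flipped to make its largest-magnitude entry positive
  (earliest index on ties), and exactly tied eigenvalues are ordered by
  the lexicographic order of their sign-fixed vectors. Individual
  eigenvectors are unstable when eigenvalues (nearly) coincide; the
  spanned subspace, all projections' norms and the energy measure are
  unaffected.
* **Numerical route.** Eigendecomposition of the $l \times l$
  covariance rather than SVD of the data matrix: `l` is at most a
  thousand or so, which keeps the decomposition cheap regardless of how
  many windows are stacked. Round-off can produce eigenvalues of order
  $-10^{-12}$; magnitudes below $10^{-10}$ are clipped to zero.
* **CV unit.** The cross-validation unit is the window, because the
  method classifies windows; per-segment majority-vote accuracy is
  reported as a secondary metric, not the headline. Folds are
  stratified by class so every fold sees every class.
* **Leakage.** Within each CV split the PCA basis, and any
  standardization statistics, are computed from the training-fold
  windows only. Refitting per fold is the conservative reading; it
  also means fold models differ slightly, which is visible as non-zero
  fold-to-fold spread on hard problems.
* **1-NN ties.** Equal distances resolve to the smallest training-set
  index — deterministic, and in practice only exercised by constructed
  inputs.
* **Trailing samples.** When `l` does not divide `N`, the tail is
  discarded with a warning rather than padded: padding would fabricate
  samples, and the discarded stretch is at most `l - 1` samples of a
  long recording.

## What the synthetic generator emulates — and what it does not

Each class is an AR(2) resonance (the simplest stationary process with
one tunable spectral peak, pole radius $e^{-\pi \cdot bw / f_s}$) scaled
by a gain, plus Poisson-placed 50 ms raised-cosine spike transients and
white measurement noise. Stationarity within windows is exactly the
regime the embedding assumes. Two presets fix the study conditions:

* **Short-segment preset** (`bonnLikePreset()`): five classes,
  20 signals/class, 4096 samples at 173.61 Hz. Two normal-like
  alpha-band classes (sd 1.0, 1.2), an interictal class away from the
  epileptogenic zone (theta, sparse small spikes, sd 1.1), an
  epileptogenic-zone interictal class (slower, spikier, sd 1.8), and an
  ictal class (3–5 Hz rhythm at gain 5, frequent large spikes). Class
  power is ordered ictal > epileptogenic interictal > normal, so the
  energy coordinate is highly discriminative for seizure detection.
* **Long-record preset** (`freiburgLikePreset()`): two classes at
  256 Hz with nearly equal power (sd 1.0 vs 1.1) but distinct peaks
  (8 Hz vs 4 Hz) — a regime where an energy-only rule performs at
  chance and only the correlation structure in the leading PCs
  separates the classes. The default volume, 16 signals/class of
  32768 samples (128 s), is a scaled-down stand-in for hour-long
  records; it was sized so that the nearest-neighbour classifier has
  on the order of a thousand training windows per class at
  `l = 512`, below which its accuracy is limited by training-set
  sparsity rather than by the features.

The generator deliberately does **not** model real EEG morphology: no
1/f background, no artifacts, no nonstationary drift between windows,
no multi-peak spectra. Passing tests on these presets therefore
demonstrate that the pipeline recovers separability that is present in
power or in spectral structure — they are not evidence about recordings
whose class differences are subtler or nonstationary.

Determinism: a dataset seed fixes every sample (per-signal seeds are
`seed + (classIndex - 1) * nSignalsPerClass + (replicate - 1)`), fold
assignment is fixed by the CV seed, and identical configurations
produce byte-identical feature CSVs and reports.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on generated
data: the short-segment preset (100 signals, 800 windows of 512) and
the long-record preset (32 signals, 2048 windows of 512), plus
randomized small-matrix comparisons against independent oracles (SVD
route for PCA, exhaustive scan for 1-NN). These sizes keep a full run
in the low minutes on one core while leaving the accuracy margins
seed-stable.

## Known limitations

* Window accuracy on windows of the *training signals'* own classes is
  an optimistic analogue of segment-level deployment; the per-segment
  majority vote is closer to clinical use but is based on few segments
  here.
* FFPC retains an odd number of components by default while narrowband
  activity projects onto quadrature *pairs* of eigenvectors; windows
  whose phase suppresses the retained member of a pair lose their
  spectral evidence. This is intrinsic to a fixed 3-D feature and is
  the main error source on the long-record preset (~0.93 rather than
  1.0).
* The method is strictly single-channel; multichannel records are
  processed channel-wise with no cross-channel fusion.
* No resampling, filtering or artifact rejection is performed; signals
  are consumed as recorded.

```{r session, eval = FALSE}
# End-to-end example: seizure detection on the short-segment preset
sigs <- generateDataset(bonnLikePreset(seed = 1))
grouped <- lapply(sigs, function(s)
    Signal(samples(s), sampleRate(s),
           if (classLabel(s) == "E") "ictal" else "rest", sourceId(s)))
evaluatePipeline(grouped, windowLength = 512, scheme = "PCPEM",
                 k = 10, seed = 7)
```
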