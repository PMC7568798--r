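---
title: "Methods: wavelet scattering for heartbeat classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet scattering for heartbeat classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scatbeat)
```

This vignette documents the model implemented by `scatbeat`, the design
decisions behind its defaults, and what the synthetic benchmark does and
does not demonstrate.

## The classification task

A beat is a 250-sample window of the modified-lead-II ECG channel at
360 Hz, cut 99 samples before and 150 samples after an annotated R-peak,
and labelled with one of the AAMI EC57 classes N, S, V, F (class Q —
paced and unclassifiable beats — is discarded, and the four records from
paced patients are excluded by default). The classifier must recognize
morphology: widened QRS complexes, missing P waves, inverted T waves,
premature timing. No denoising or baseline correction is applied; the
classifier sees the raw samples in mV.

## The scattering transform

The feature extractor cascades wavelet convolutions, a complex modulus,
and low-pass averaging:

* order 0: `f ⋆ φ` — the local average of the beat;
* order 1: `|f ⋆ ψ_λ1| ⋆ φ` — envelopes of band-passed components;
* order 2: `||f ⋆ ψ_λ1| ⋆ ψ_λ2| ⋆ φ` — amplitude-modulation structure of
  those envelopes.

The averaging makes the coefficients invariant to translations up to
roughly the invariance scale `T`, and the modulus makes the cascade
nonexpansive (a Lipschitz bound with constant 1), which is what gives the
features their stability to small time warps. Energy beyond order 2 is
negligible for this class of signals, so the cascade stops there. No
logarithm or renormalization is applied to the coefficients.

### Architecture parameters

| parameter | default | units | role |
|---|---|---|---|
| `sampling_rate` | 360 | Hz | input rate |
| `invariance_scale` (T) | 0.5 | s | time support of the Gaussian low-pass; invariance horizon |
| `q_factors` | 8, 1 | wavelets/octave | frequency resolution of layers 1 and 2 |
| `max_order` | 2 | — | cascade depth |
| `signal_length` | 250 | samples | beat length |
| `oversampling` | 0 | log2 factor | denser output grids on demand |

T = 0.5 s covers most of a beat-to-beat interval, so the features describe
one beat rather than its exact phase; Q = 8 in the first layer resolves
the narrow spectral features of the QRS complex while Q = 1 suffices for
the broad envelopes reaching the second layer. Under these defaults a
250-sample beat yields 75 scattering paths (1 + 41 + 33) with 8 time
windows each.

### Filter-bank design

The filters are Gabor (analytic Morlet) wavelets: Gaussian bumps in
frequency, with an exact DC correction so every wavelet has zero mean on
the discrete frequency circle. Three constants, frozen in the package,
complete the design that the architecture parameters leave open:

* **Low-pass width.** `σ₀ = 2√(2 ln 2)/(2π) ≈ 0.375` in units of 1/T, so
  the time-domain full width at half maximum of φ equals T exactly — the
  sense in which T is the filter's "time support". The coarsest wavelets
  share this bandwidth floor, so no filter is wider in time than φ.
* **Overlap.** Within the constant-Q (geometric) regime, adjacent filters
  cross at half power (`r = √½`). Below the frequency where a constant-Q
  filter would become narrower than the low-pass, the first layer
  continues with fixed-bandwidth filters spaced at 0.6 of their half-power
  bandwidth, down to the low-pass bandwidth itself; this keeps the
  low-frequency band covered without ripple collapse. The second layer
  (Q = 1) reaches its floor within the octave progression and needs no
  linear tail.
* **Path pruning.** A second-order path (λ1, λ2) is kept only when the
  center frequency of ψ_λ2 lies below the half-power bandwidth of ψ_λ1 —
  paths that would carry no envelope energy are never computed.

Each layer is then scaled so its Littlewood–Paley sum
`|φ̂|² + ½Σ(|ψ̂(ω)|² + |ψ̂(−ω)|²)` attains 1 but never exceeds it: the
bound guarantees nonexpansiveness, attaining it keeps the layers close to
energy-preserving. For this design the sum stays within [0.70, 1] over
each layer's covered band; the 0.70 ripple floor is asserted in the test
suite as a property of the frozen design.

### Discretization

Beats are reflection-padded (symmetric, edge sample repeated) to the next
power of two — 250 → 256 — before FFT convolution; reflection avoids the
edge spikes circular convolution would create on beats truncated
mid-waveform. Convolutions are zero-phase products in the frequency
domain. Outputs are critically downsampled with hop
`2^(⌊log₂(T·fs)⌋ − 2)` = 32 samples: the critical rate for the low-pass
bandwidth with a two-octave guard against aliasing the modulus envelopes,
and the rate at which a 256-sample padded beat yields exactly 8 windows.
Window centers sit at padded positions 16, 48, …, 240, i.e. samples
13, 45, 77, 109, … of the unpadded beat; the fourth window (0-based
index 3, center 109) spans the R-peak region, which is why it carries most
of the class information. `oversampling = k` halves the hop k times.
Signals containing NA or non-finite values, and signals of the wrong
length, are rejected rather than patched.

## Window reduction

The 8 windows of one beat are strongly correlated, and they are reduced
before classification in one of three ways:

* `window:<i>` — one window per beat (75 features). Index 3 is the
  default working point.
* `windows:<i,j,...>` / `windows-all` — each selected window becomes its
  own classification row; the per-window decisions are merged per beat by
  majority vote, ties broken by the largest summed confidence (softmax or
  PNN posterior; negative mean neighbour distance for KNN).
* `pca1` — for each of the 75 paths independently, the windows are
  treated as 8 variables over beats, and each beat is projected on the
  leading eigenvector of the 8×8 covariance (covariance, not correlation:
  the windows share units and their scale is informative). Eigenvector
  signs are fixed by making the largest-magnitude loading positive;
  zero-variance paths score 0 with a warning. Contribution rates are
  averaged as per-path eigenvalue fractions. In cross-validation the
  component is fitted on the training folds by default; `reduce_on_all =
  TRUE` reproduces the simpler fit-on-everything protocol.

## Classifiers

* **KNN** (`k = 4`, Euclidean). An even k needs a tie rule: a tie between
  classes is resolved by the class of the single nearest neighbour among
  the tied classes — a deterministic rule that degrades gracefully to
  1-NN.
* **PNN** (`spread = 0.01`). Class score = mean Gaussian kernel
  `exp(−‖x−xᵢ‖²/2σ²)` over the class's pattern units (mean rather than
  sum, so the score is a density estimate even if training classes are
  not perfectly balanced); posteriors are the normalized scores. The
  spread is a length in feature space, so its useful value depends on the
  feature scale; 0.01 is the working point for raw scattering
  coefficients of mV-scale beats. As σ → 0 the classifier reduces to
  1-NN, which is also the explicit fallback when every kernel underflows.
* **Feedforward network**: layers 75-70-60-45-30-20-10-4, ReLU on all six
  hidden layers (the published description activates the first five and
  leaves the sixth unstated; uniformity is the simpler choice and is
  configurable), softmax output, categorical cross-entropy, Adam
  (β₁ = 0.9, β₂ = 0.999, ε = 1e−8), 50 epochs. Minibatch size (256) and
  learning rate (1e−3) are not pinned by the published description and
  are exposed as arguments. He-scaled Gaussian initialization; training
  is deterministic given the seed; a non-finite loss aborts with a
  diagnostic rather than returning a broken model. The parameter count of
  the default architecture is 14579.

## Evaluation protocol

Folds are stratified by class (the published protocol says only "divided
into 10 equal parts"; stratification makes the folds exchangeable and is
near-automatic once classes are balanced), with remainders rotated across
classes so fold sizes differ by at most one, and seeded shuffling for
reproducibility. Confusion counts are accumulated across folds, so every
beat is tested exactly once and row sums equal class totals — an
invariant the tests assert. Per-class metrics are one-vs-rest
PPV/SEN/SPEC; the binary collapse treats N as negative and any abnormal
class as positive, so a beat predicted S when it is truly V still counts
as a true positive. Zero-denominator metrics are reported as `NA`, never
as 0. Metrics print at one decimal in percent.

Augmentation (subsample the majority class to the target, top up minority
classes with noisy copies, Gaussian noise of variance 0.05 mV²) is applied
to the whole dataset before fold splitting, matching the published
ordering. This means noisy copies of one source beat can land in both
training and test folds — an optimistic bias inherent to that protocol.
Keeping augmentation inside the training folds, or grouping folds by
source beat, avoids the leak at the cost of no longer matching the
published pipeline; the augmentation step is exposed separately precisely
so either ordering can be composed.

## The synthetic generator

`generate_dataset()` draws beats as sums of Gaussian components (P, Q, R,
S, T waves) with per-component amplitude/width/position jitter and white
baseline noise, R wave at sample 99. The four templates encode textbook
class morphology: N has a full P-QRS-T; S shortens the pre-R interval and
shrinks the P wave; V widens the QRS, drops the P wave and inverts the T
wave; F blends N and V. The class means are pairwise distinguishable
(pinned correlation bounds in the tests), so pipeline tests are
non-vacuous.

What the generator does *not* emulate: recording noise and baseline
wander, electrode artefacts, rhythm context (RR-interval dynamics),
inter-patient morphology variation, or the severe class imbalance of real
arrhythmia data. A pipeline that reaches ≥ 95% accuracy on the synthetic
benchmark is demonstrably wired correctly end to end; that figure says
nothing about accuracy on clinical recordings, which must be measured on
real WFDB data. The synthetic WFDB writer exists to exercise the readers,
not to simulate a Holter recording.

## Problem sizes and tolerances

The test suite and the bundled benchmark run at desk scale by design: 200
beats per class for the end-to-end separability bar, tens of beats for
protocol tests, length-64 signals for the O(N²) direct-convolution oracle
(FFT vs direct agreement within 1e−8 relative error), and short carrier
vectors for the balancing-arithmetic check, whose counts — 90023 N, 2758
S, 6914 V, 800 F to a target of 90000 per class, 360000 beats in total —
do not depend on the beat length. Nonexpansiveness is asserted with a
1e−6 relative slack for floating-point rounding; translation stability is
asserted as a monotone trend over circular shifts of 1–8 samples with
relative feature change below 5%.

## Known limitations

* Intra-patient evaluation: beats from one recording can appear in both
  training and test folds. Patient-wise splits are a different, harder
  protocol and are out of scope here.
* R-peaks come from reference annotations; no detector is bundled.
* The WFDB reader covers header/signal formats 212 and 16 and MIT-format
  annotations — sufficient for MIT-BIH-style records, not a general WFDB
  implementation.
* The PNN stores the full training set; with hundreds of thousands of
  pattern units, prediction cost is driven by the training-set size.
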