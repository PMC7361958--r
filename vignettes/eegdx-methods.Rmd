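---
title: "Methods: sub-band wavelet features and cross-validated EEG classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sub-band wavelet features and cross-validated EEG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegdx)
```

## The diagnostic model

`eegdx` treats EEG-based disorder screening as a supervised classification
problem over spectral summary statistics. The working assumption is that the
conditions of interest shift the *distribution of signal energy across the
canonical EEG rhythms*: epileptiform activity adds heavy-tailed transient
energy and slow-wave power, while resting-state ASD profiles are
characterized by altered slow (delta/theta) and gamma power relative to
alpha. A classifier over per-rhythm statistics can then separate classes
without modeling waveform morphology.

The processing chain is fixed: read → ocular artifact removal → 50 s
segmentation → elliptic band-pass → 4-level DWT → per-sub-band statistics →
k-fold cross-validated classification. Each stage is exposed as an ordinary
function on tibbles or light S3 records, so the chain can be run whole
(`run_pipeline()`) or stage by stage.

## Sub-band decomposition

Segments are decomposed with a 4-level discrete wavelet transform using the
Daubechies db4 mother wavelet, producing detail coefficients D1–D4 and the
final approximation A4. Nominal band edges follow from halving the Nyquist
interval: at fs = 256 Hz, D1 = (64, 128], D2 = (32, 64], D3 = (16, 32],
D4 = (8, 16] and A4 = (0, 8] Hz. We deliberately derive these bands from the
actual sampling rate rather than hard-coding textbook rhythm edges: fixed
printed ranges such as "D1: 30–60 Hz, A4: 0.1–4 Hz" are only consistent
with a sampling rate near 240 Hz and match neither 173.61 Hz nor 256 Hz
material. The conventional rhythm names (gamma/beta/alpha/theta/delta) are
therefore kept as *display aliases* of D1–A4, not as frequency guarantees.

The boundary extension is periodized orthonormal by default. This choice is
what makes the transform an orthogonal map on even-length inputs, giving two
exact invariants the test suite checks numerically: coefficient energy
equals signal energy, and the inverse transform reproduces the input, both
to better than 1e-8 relative error (measured at ~1e-16 on dyadic lengths).
Odd lengths at any level are handled by repeating the final sample; the
4097-sample single-channel signals of the classic epilepsy sets pass through
unchanged apart from that one-sample pad. Features are computed on the raw
coefficients, not on reconstructed band signals: the statistics are energy
functionals, and the orthogonality of the transform makes per-band
coefficient energy the natural carrier of band power.

## The five statistics

For a coefficient sequence $S_n$, $n = 1..N$:

* variance $V = \frac{1}{N}\sum_n (S_n-\mu)^2$ and its square root, the
  standard deviation — population (divisor-$N$) moments, not sample
  moments;
* kurtosis $E[((S-\mu)/\sigma)^4]$ in the non-excess convention, so a
  Gaussian signal scores 3. A constant sequence has undefined kurtosis and
  raises an error by default; batch runs can map it to a 0 sentinel
  (`kurtosis_degenerate = "zero"`);
* non-normalized Shannon entropy $\sum_n S_n^2 \log S_n^2$ with the
  convention $0\log 0 = 0$. The formula is implemented exactly as stated,
  without a leading minus sign — the sign is a global flip that no
  classifier can distinguish;
* logarithmic band power $\log\left(\frac{1}{N}\sum_n S_n^2\right)$. An
  all-zero band would be $-\infty$ and raises an error unless a finite
  floor is supplied.

The logarithm base is unspecified in common usage; we fix the natural log
(configurable to base 10). The base scales entropy and LBP by a constant, so
it cannot change any classification result, but it must be pinned for
reproducibility. Every statistic is checked against an independent
brute-force loop over its formula at 1e-12 relative tolerance.

Feature vectors are ordered channel-major, then sub-band in the fixed order
D1, D2, D3, D4, A4, then statistic. Multi-channel segments concatenate
channels (23 channels × 5 bands = 115 features per statistic); per-channel
ordering is file order, which is therefore part of the I/O contract.

## Filtering

The band-pass is an elliptic (Cauer) design, 0.1–60 Hz by default, with
0.5 dB passband ripple and 40 dB stopband attenuation at prototype order 8 —
standard EEG practice where only the band itself is dictated by the
workflow. Two implementation choices matter numerically:

* **Zero-pole-gain design realized as biquad cascades.** With a passband
  edge at 0.1 Hz and fs = 256 Hz, transfer-function (b, a) coefficients of
  a high-order design are unusable: expanding the denominator polynomial
  pushes near-unit-circle poles outside the circle (we measured
  max |pole| ≈ 1.0086 for a direct order-16 design). The package computes
  the analog elliptic prototype from Jacobi elliptic functions, applies the
  low-pass→band-pass transform and the bilinear map in zero-pole-gain form,
  and pairs conjugate roots into second-order sections — the same
  architecture scipy uses. The realized response is validated in tests
  against its own design template (passband within ripple, stopbands at or
  below the attenuation target). After section assembly the passband peak
  is rescaled to exactly unity gain, compensating sub-0.02 dB
  special-function accumulation.
* **Zero-phase application by default.** Features are spectral statistics;
  phase distortion would be gratuitous, so each section is run forward and
  backward (`filtfilt`). This squares the magnitude response — the
  effective passband loss doubles in dB — which the tests account for. A
  causal single-pass mode is available.

A 60 Hz notch biquad is provided but off by default: for 173.61 Hz material
the notch sits at the band edge and mostly duplicates the band-pass.

## Ocular artifact removal

Multi-channel recordings with flagged EOG reference channels are cleaned by
FastICA (symmetric orthogonalization, tanh contrast) on the scalp channels.
Components whose absolute Pearson correlation with any EOG reference
exceeds 0.7 (configurable) are zeroed before reconstruction, and the EOG
channels are dropped from the output. The initialization is seeded and
deterministic; non-convergence triggers one retry with a shifted seed
before raising. Recordings with no EOG reference, or with a single scalp
channel (where ICA is mathematically impossible — in particular all
single-channel dialects), pass through unchanged with an empty report. An
adaptive-filter (LMS/RLS) EOG canceller is deliberately out of scope.

## Segmentation policy

The standard window is 50 s, non-overlapping. Because important
single-channel reference material is only ~23.6 s long, a plain "drop the
tail" rule would discard such recordings entirely. The default policy
`whole-if-shorter` therefore behaves like `drop` except that a recording
shorter than one window yields a single flagged short-tail segment covering
the whole recording; `drop` and `keep-short` are selectable.

## Classifiers and cross-validation

* **LDA** (`MASS::lda`), unstandardized — it is scale-equivariant.
* **Linear SVM** (`e1071::svm`, cost 1) with one-vs-all fusion: one binary
  machine per class, each oriented so positive decision values favor its
  target class, fused by maximum decision value. libsvm's native multiclass
  mode is one-vs-one, so the OvA layer is built explicitly.
* **KNN**, k = 5, Euclidean distance, written in-package because the
  standard implementation breaks voting ties at random. Here neighbors tied
  with the k-th distance all vote; vote ties go to the class with the
  nearer nearest neighbor, then to fixed class order
  (neurotypical < epilepsy < autism). Prediction is fully deterministic.
* **ANN** (`nnet`), one hidden layer of 5 nodes, softmax output, small
  weight decay. Early stopping monitors cross-entropy on a stratified 10%
  split of the training fold, trains in 25-epoch rounds with patience 4,
  and keeps the best-validation weights; the epoch budget defaults to 300.

Features are z-scored per training fold for SVM/KNN/ANN (distance- and
margin-based methods should not see microvolt-scale variance features next
to log-scale LBP features); scaling parameters are estimated on the
training fold only and applied to the held-out fold, so no test statistics
leak.

Folds are stratified by class by default, assigned round-robin after a
seeded shuffle, which bounds per-fold class imbalance at one sample.
Per-fold accuracy is 100·correct/held-out; the summary accuracy is the
exact arithmetic fold mean and the quoted ± value is the across-fold
standard deviation (the natural reading of fold averaging when the
dispersion convention is not otherwise defined). Fold granularity is the
*segment*, matching the workflow this package reimplements; because
segment-level folding can leak subject identity when several segments come
from one subject, `group_folds = TRUE` assigns whole subjects to folds
instead. Both modes are first-class; the default favors fidelity, the
option favors rigor. `run_grid()` evaluates every (statistic, classifier)
cell on one shared fold partition so cells are directly comparable.

## The synthetic generator

`generate_segment()` builds each channel as a sum of one oscillator per
rhythm at fixed canonical centers (delta 2, theta 6, alpha 10, beta 20,
gamma 40 Hz) with seeded random phases, amplitudes proportional to the
square root of the requested relative band powers, plus 1/f^a background
noise at 20% of oscillator power (configurable, 0 disables), all scaled to
an overall amplitude in µV. Epileptiform activity is emulated by Poisson
spike trains of ~60 ms biphasic transients at 8× the signal scale — enough
to dominate kurtosis, as in real interictal spikes. Eye blinks are planted
as 400 ms raised-cosine transients at 5× the per-channel standard
deviation, mirrored at double gain on a synthetic EOG channel, making ICA
removal demonstrably effective and measurable against the known blink
train.

The three presets (`spec_neurotypical()`, `spec_epileptic()`,
`spec_autistic()`) encode alpha-dominant, spike-rich and
elevated-delta/theta/gamma profiles respectively. These profiles are the
package's chosen study conditions for its recovery experiments: 100
segments per class of 50 s at 256 Hz, 10-fold CV.

What the generator does *not* emulate: volume conduction and realistic
channel covariance (channels are independent realizations), non-stationary
rhythm dynamics, seizure evolution beyond spike trains, muscle or electrode
artifacts. Passing recovery tests therefore demonstrates that the pipeline
measures and separates the spectral structure it claims to measure — not
that real-data accuracies are reproduced. Headline accuracies on the
published external datasets require those datasets; the manifest/EDF/ASCII
readers support them, and the label-permuted null calibration (accuracy
statistically at chance) guards against the pipeline manufacturing
separation that is not in the data.

## Numerical choices and degenerate inputs

* DWT requires segment length ≥ 2⁴ × filter support (128 samples for db4);
  shorter segments raise a length error naming the minimum.
* Energy/reconstruction tests run at 1e-8 relative tolerance on dyadic
  lengths; statistic-oracle equivalence at 1e-12.
* EDF quantization: each channel is calibrated to its own physical range
  over the 16-bit digital range, so round-trip error is bounded by one
  step of (max−min)/65535.
* ICA convergence tolerance 1e-7, 200 iterations, one seeded retry.
* All randomness flows through explicit integer seeds (`withr::with_seed`),
  leaving the global RNG untouched; generation, folding and training are
  reproducible bit-for-bit for the deterministic classifiers.

## Test problem sizes

The suite exercises the full study conditions where the experiment is the
point (100 × 50 s segments per class for the recovery and null
experiments) and smaller configurations (2–30 segments, 2–16 s) where only
contracts are under test; the complete suite runs in well under a minute on
one core.

## Known limitations

* The elliptic design supports prototype orders ≥ 1 but extremely narrow
  relative bands at very low sampling rates can still produce
  ill-conditioned sections; the design aborts rather than returning an
  unstable filter.
* The ANN's early stopping uses a fixed round length (25 epochs) rather
  than per-epoch monitoring, trading granularity for speed.
* libsvm exposes a convergence tolerance rather than an iteration cap, so
  the spec-level `max_iter` maps onto that tolerance for the SVM.
* EDF support covers continuous uniform-rate recordings; EDF+ annotations
  and discontinuous files are out of scope, as are BDF/BrainVision formats.
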