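---
title: "Camera pulse signals to vitals and a synthetic single-lead ECG: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Camera pulse signals to vitals and a synthetic single-lead ECG: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`ppgvitals` implements a complete pipeline for camera-based
photoplethysmography: a fingertip pressed on a phone camera modulates the
reflected light with each heart beat, and the spatial mean of the frames is
a pulse waveform (the video-PPG). From that waveform the package estimates
heart rate (HR, beats/min), blood oxygen saturation (SpO2, %) and
respiratory rate (RR, breaths/min) with compact neural regressors, and
synthesizes a single-lead ECG by cycle-wise regression in the discrete
cosine transform (DCT) domain.

All training and evaluation can run against a built-in synthetic
paired-signal generator, so nothing in the package requires clinical data.

# The synthetic generator and what it emulates

`sim_config()` fixes the study conditions of a synthetic recording. The
generator emulates the features of real paired fingertip-video/ECG data
that the downstream methods rely on:

* **ECG morphology.** Each cardiac cycle is the sum of five Gaussian bumps
  (P, Q, R, S, T) at fixed phase angles — the classical sum-of-Gaussians
  ECG parameterization (angles about -70, -15, 0, 15, 100 degrees;
  amplitudes 1.2, -5, 30, -7.5, 0.75 rescaled to a unit R-peak; widths
  0.25, 0.1, 0.1, 0.1, 0.4 rad). Cycle lengths follow the configured HR
  with a small respiratory-sinus modulation (`rsa_frac`, default 2%).
* **Pulse-transit lag.** Every PPG pulse peak trails its R-peak by
  `ptt_lag` milliseconds (default 200 ms), which is what cycle pairing
  must estimate and remove.
* **Respiration.** Baseline wander (`drift_amp`) and pulse-amplitude
  modulation (`am_frac`) at the RR frequency; this is the information the
  RR regressors and the drift-removal filter act on.
* **SpO2 encoding.** The red/green AC/DC amplitude ratios are set so that
  the ratio-of-ratios statistic R satisfies SpO2 = 110 - 25 R, the
  textbook affine pulse-oximetry calibration. Real phone cameras need a
  device-specific calibration; this fixed convention exists so that
  learned models can be *tested for recovery* of a known encoding, not to
  claim camera realism.
* **Frames.** `gen_frames()` renders each PPG sample as a frame of
  constant intensity plus per-pixel Gaussian noise, quantized to 8 bits,
  so pixel averaging over a region of interest recovers the waveform up to
  quantization (a 0.5 intensity-unit bound plus the central-limit term
  `3 * spatial_sd / sqrt(n_pixels)`).

What the generator does **not** emulate: motion artifacts and finger
repositioning, camera auto-exposure and white balance, sensor rolling
shutter, inter-subject morphology differences beyond rate/lag/amplitude
parameters, and arrhythmic beats. Tests passing on these fixtures
demonstrate that the algorithms are implemented correctly and can recover
planted structure; they do not establish clinical accuracy on real
recordings.

Default noise (`noise_sd = 0.02` of the pulsatile amplitude) and the
per-recording HR / pulse-transit ranges used in the benchmarks (55-110
beats/min, 150-250 ms) are in the middle of the physiological range for
healthy adults at rest.

# Preprocessing

**Wavelet filtering.** A five-level fast wavelet transform (Daubechies
db4 by default) decomposes the signal; the deepest approximation band
(respiratory and ambient-light baseline) and the two finest detail bands
(high-frequency noise and motion artifacts) are zeroed before
reconstruction. No wavelet package is relied on: the transform is a
direct Mallat pyramid with periodized filtering after symmetric padding
to a multiple of `2^levels`, which keeps perfect reconstruction exact for
any input length (verified to 1e-9 in the tests). The five-level rule
interacts with the sampling rate: at the 30 Hz video frame rate the
retained bands span about 0.5-3.8 Hz, bracketing the cardiac fundamental;
at 125 Hz they span about 2-16 Hz, so the pulse fundamental itself falls
into the discarded approximation band and the filtered PPG keeps only
the pulse's upstroke/dicrotic structure. Peak detection and cycle
pairing are built to work on either form, but envelope landmarks are
sharpest at the video rate.

**Envelope detrending.** Natural cubic splines through the detected
valleys (lower envelope) and peaks (upper envelope) normalize the signal
to `(x - lower)/(upper - lower) - 0.5`, so peaks sit at +0.5 and valleys
at -0.5. Outside the outermost fiducials the envelopes are clamped to
their nearest value rather than extrapolated (spline extrapolation is
unbounded); spline overshoot beyond 0.05 between fiducials triggers a
warning. A degenerate envelope (upper below lower) is an error that names
the first offending sample.

**Segmentation.** Windows of `w_s` seconds advance with a 1 s stride;
each window's label is the mean of the per-second labels it spans, giving
`T - w_s + 1` windows for a T-second recording. Window arithmetic is done
in whole samples and `w_s * fs` must be integral. Defaults are 10 s for
HR and SpO2 and 30 s for RR — respiration is slow (one breath every 3-4
s), so RR windows must span several breaths.

# Peak detection

`terma_detect()` implements the two event-related moving averages scheme:
the rectified-squared signal is smoothed with a short window spanning the
event (QRS complex or systolic upstroke) and a long window spanning about
one beat; blocks where the event average exceeds the cycle average
inflated by `offset_beta` are candidate events, blocks shorter than the
event window are dropped, and each surviving block contributes its signal
argmax (earliest sample on ties). Two implementation choices matter:

* The block threshold adds an absolute guard `offset_beta * mean(energy)`
  to the relative criterion; without it, stretches of near-zero cycle
  average between widely spaced beats admit noise-only blocks. The guard
  is quadratic in the signal, so detection stays invariant under positive
  affine transforms of the input.
* A 1-second moving-average baseline is subtracted before rectification,
  so raw drifting inputs and filtered ones are detected alike; block
  argmaxes are still taken on the original samples.
* A refractory `min_separation` keeps the larger of two conflicting
  peaks. For ECG it is fixed at 200 ms; for PPG it adapts to the data:
  0.55 of the beat period, estimated as the lowest line of the energy
  spectrum within 0.5-3.4 Hz reaching 35% of the band maximum. The
  adaptive form matters on filtered PPG, where removal of the sub-2 Hz
  fundamental can make the dicrotic wave as tall as the systolic one.

Window defaults (event 97 ms / cycle 611 ms for ECG R-peaks, 111 / 667 ms
for PPG pulse peaks, `offset_beta` 0.08) follow the published values of
the two-moving-average detector family; all are per-recording tunable,
which is also the escape hatch for unusual morphologies where a manual
threshold adjustment is needed.

`locate_pqrst()` finds the remaining ECG fiducials in fixed physiologic
windows around a known R-peak (Q and S as minima within 80 ms before and
after; P as the maximum 250-80 ms before; T as the maximum 80-400 ms
after). A window that exceeds the cycle bounds marks that fiducial
absent rather than guessing.

# Vitals regressors

Three small models map a segment to its vitals, all trained with Adam
under the mean-absolute-error criterion (robust to label outliers),
batch size 128, up to 1000 epochs with early stopping (patience 20) and
plateau learning-rate decay (factor 0.1):

* **cnn_net** — short-time Fourier magnitude front-end, three 1-D
  convolution blocks (16/32/64 filters, kernel 5, max-pool 2), then
  flatten, batch-norm, dropout, a dense layer and the linear output;
  batch normalization and dropout follow the flatten and every dense
  layer.
* **mt_net** — orthonormal type-II DCT front-end with an additive skip
  (the input is added to its transform, so both waveform and spectrum are
  visible to the convolutions), the same convolution stack, and a relu
  fully-connected head.
* **vit_net** — the STFT image grouped into 16 token patches, linearly
  embedded to width 64, passed through two pre-layernorm transformer
  blocks (single-head attention + gelu MLP), mean-pooled and read out.

Inputs are z-scored globally per dataset; labels are z-scored per vital
by default (`scale_labels`), which balances the three vitals in the
joint configuration — predictions are mapped back to physical units.
Output width is 1 in the vital-specific configuration and 3 when all
vitals are stacked jointly.

The entire neural stack (dense, 1-D convolution via im2col, batch/layer
normalization, dropout, single-head attention, Adam, schedules, early
stopping with best-weight restoration) is implemented in-package in plain
R matrix arithmetic. Every layer's analytic gradient is checked against
central finite differences in the test suite, and training is
bit-reproducible for a fixed seed in single-threaded execution.

Evaluation follows a leave-several-subjects-out (LESSO) protocol:
`lesso_split()` holds out whole subjects (default 5) so no held-out
subject contributes any window to training, and per-subject MAEs are
summarized by their mean and standard deviation. `window_size_search()`
re-segments and retrains across a grid of window lengths, reporting MAE
and SAE (the population standard deviation of the absolute errors — the
same divide-by-N convention used for the across-subject spread).

# Contrastive caption retrieval

The retrieval model embeds PPG segments and vitals captions into a
common 256-dimensional space. Captions are deterministic templates
("HR is 72 beats/min, SpO2 is 97 %, RR is 16 breaths/min", optionally
with SBP/DBP in mmHg) that parse back exactly via unit-anchored
patterns; fields a caller does not request are simply ignored, so a bank
mixing blood-pressure captions is harmless.

The PPG encoder follows the printed architecture: four 1-D convolutions
(8, 8, 16, 32 channels; kernels 10, 5, 3, 3; stride 1; pool 2 after the
first two), which takes a 1250-sample input to a 9728-wide flatten, then
a projection head (dense to 256, a residual gelu-dense-dropout block,
layer normalization). Where the printed filter/kernel column conflicts
with the printed output shapes, the output-shape column is followed. The
text encoder is a trainable token-embedding bag (whitespace tokenizer
that keeps numbers whole) mean-pooled into the same projection head — a
deliberately lightweight choice so the package builds and trains fully
offline; a pretrained language encoder could be substituted for the
embedding bag without touching the contrastive machinery.

Pretraining minimizes the symmetric cross-entropy over the in-batch
similarity matrix of L2-normalized embeddings with a learnable
temperature (initialized at 1/0.07). Querying embeds a segment, ranks a
caption bank by dot product, parses the top-k captions (k = 3 by
default) and averages each vital over the captions that contain it.

# PPG-to-ECG translation

Both signals are wavelet-filtered, detrended to the centred unit scale,
and cut into cardiac cycles. During training, each R-peak is matched to
the following pulse peak, the pulse-transit lag is estimated as the
median offset and removed, and both traces are cut at reference points
placed 35% of the median beat before each R-peak — so the full P-QRS-T
complex lies inside one cycle. Every cycle is linearly resampled to a
common length L = 300 samples (about 2.4 s of headroom at 125 Hz, enough
for beats down to 25/min before truncation), and represented by its
leading 150 orthonormal type-II DCT coefficients; at that truncation a
smooth ECG cycle reconstructs with under 2% relative error while the
dimension halves.

The regression from PPG coefficients to ECG coefficients comes in two
configurations:

* **ridge** — the closed-form penalized least-squares map on centred
  coefficients, `(X'X + lambda I)^(-1) X'Y` (default `lambda` 1e-3);
* **ffnn** — two hidden layers of 175 units (selu activation, batch
  normalization, L1 weight penalty 1e-5), Xavier initialization, Adam
  with MAE loss, batch 100, staircase exponential learning-rate decay
  (factor `exp(-0.1)` every 50 epochs), up to 1000 epochs with early
  stopping and best-weight restoration. The hidden width 175 puts the
  parameter count near 84 k. The selu default follows the architecture's
  textual description; tanh is selectable where that reading is
  preferred. The printed "decay rate exp(0.1)" is read as a decay — a
  factor above one would grow the learning rate — hence `exp(-0.1)` per
  staircase step.

Coefficients are centred per dimension and scaled by a single global
standard deviation on each side before the network (preserving the
relative weighting of the coefficients, unlike per-coefficient
z-scoring, while conditioning the optimization).

At test time no ECG and no synchronization are needed: the PPG alone is
cut at its pulse peaks, translated cycle by cycle, inverse-transformed,
and resampled back to each beat's native length so the synthetic ECG
keeps the subject's rhythm.

Evaluation is cycle-level: Pearson correlation, MAE on the detrended
scale, the worst-case pointwise distance (the printed definition's outer
minimum over the single index set [1, N] is vacuous and implemented as
the identity), and a per-fiducial amplitude-error table (P/Q/R/S/T) with
means and across-subject standard deviations. Amplitude errors are taken
at the reference cycle's fiducial sample index by default; re-detection
on the reconstruction is available as a switch.

# Problem sizes and numerical choices

The shipped tests and the benchmark script use these scales, chosen so a
full run is comfortable on a single desktop core:

* ECG-synthesis benchmark: 1800 preprocessed synthetic cycle pairs
  (about thirty 60 s recordings), 1500 for training, 300 held out; the
  feed-forward configuration trains in roughly a minute and reaches a
  mean held-out cycle correlation above 0.8 with mean MAE below 0.1 on
  the detrended scale.
* HR recovery: about 3000 ten-second segments from 25 synthetic subjects
  at 30 Hz; fifteen epochs of the DCT-front-end regressor reach a
  held-out MAE under 3 beats/min (typically near 1).
* Contrastive retrieval is exercised at reduced geometry (250-sample
  segments, a trimmed encoder) where pretraining separates matched pairs
  within 25 epochs; the full 1250-sample encoder is validated
  structurally (flatten width, embedding norms, determinism).

Degenerate inputs are errors, not silent repairs: empty ROIs, envelopes
that cross, windows longer than the recording, non-integral `w_s * fs`,
fewer than two fiducials, constant inputs to the correlation. Ties in
block maxima resolve to the earliest sample; trailing samples that do
not fill a pooling window are dropped; batch-norm running statistics use
momentum 0.9; Adam uses the standard (0.9, 0.999, 1e-8) constants.

# Known limitations

* The generator's SpO2 calibration is a fixed documented convention, not
  a camera model; learned SpO2 heads recover the planted encoding only.
* The text encoder is an embedding bag: it cannot generalize to caption
  wordings far from the training templates.
* Single-head attention and two blocks make the transformer a minimal
  stand-in, not a tuned architecture.
* Pure-R training is practical at the package's problem sizes but not
  for corpora orders of magnitude larger.
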