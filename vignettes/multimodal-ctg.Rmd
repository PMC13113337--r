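---
title: "Multimodal CTG classification: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal CTG classification: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctgfuse)
```

## Overview

`ctgfuse` classifies 30-minute intrapartum cardiotocography (CTG) segments
as normal or abnormal by fusing three views of the same labor episode: the
raw two-channel time series (fetal heart rate, FHR, and uterine
contractions, UC, both at 4 Hz), a Gramian Angular Difference Field (GADF)
image of the FHR, and a four-variable maternal metadata vector. This
vignette explains the model and its assumptions, the tunable parameters and
their defaults, what the synthetic generator does and does not emulate, and
the numerical and design decisions taken where the architecture left choices
open.

## Preprocessing

Clinical CTG is full of sensor dropouts and motion artifacts, so cleaning
precedes everything:

* **FHR validity.** A sample is invalid when it lies outside the
  physiologically plausible 50–220 bpm band, or when it changes by more than
  25 bpm relative to the most recent *in-range* sample (the later sample of
  the offending pair is flagged). Comparing against the last in-range sample
  rather than the raw predecessor means a single out-of-range excursion does
  not condemn the healthy sample that follows it, while a genuine in-range
  spike flags only itself and at most its immediate successor. A plain
  adjacent-sample comparison and a "most recent unflagged sample" comparison
  were both considered; the first flags the recovery sample after every
  out-of-range artifact, the second invalidates the entire tail after a
  legitimate baseline shift.
* **UC validity.** The 3σ (Pauta) rule over a centered sliding window of 500
  samples, truncated at the boundaries; sequences shorter than the window
  use the whole sequence. Windows with zero local standard deviation flag
  nothing — any other convention would flag all or nothing of a constant
  stretch arbitrarily. Local standard deviations use the sample (n−1)
  convention; the brute-force oracle in the test suite recomputes the same
  definition per sample.
* **Reconstruction.** Invalid runs are linearly interpolated between the
  nearest valid neighbours; leading/trailing runs take the nearest valid
  value. A record with no valid samples is unrecoverable. Because valid FHR
  samples lie in [50, 220], interpolation and the subsequent smoothing
  cannot leave that interval.
* **Smoothing.** The reference pipeline applies an unspecified smoother;
  this package uses a centered moving average of width 5 samples (1.25 s at
  4 Hz), the simplest low-pass filter consistent with the intent, width
  configurable and width 1 the identity.
* **Eligibility.** A record qualifies when its signal-loss rate is strictly
  below 50%.

## The three encoders

**Signals.** Each channel is instance-normalized (per-record, per-channel
z-score with the population standard deviation and an `eps = 1e-5` guard;
constant channels map to zeros), cut into overlapping patches of length
`patch_length = 64` at `stride = 32` (the tail zero-padded so the last patch
is full, `N = ceiling((L-P)/S) + 1`), linearly embedded into
`d_model = 128`, given learnable positional embeddings, and run through a
transformer encoder whose weights are *shared* between channels while the
channels are processed independently — FHR and UC have different physiology,
so cross-channel attention is deliberately avoided. Mean pooling over
patches and concatenation (FHR first) give a `2 * d_model` vector. The
encoder's internal dimensions (depth 3, 4 heads, feed-forward width 256,
dropout 0.1) are not dictated by the reference architecture; the defaults
here are the smallest configuration in common use for patch-based
time-series transformers, and every one of them is configurable.

**Image.** The cleaned FHR is min–max rescaled into `[a, b] = [-1, 1]`
(a constant series maps to the interval midpoint so fully interpolated
segments still produce an image), mapped to polar angles `acos(x)`, paired
into the Gramian `G[i,j] = cos(phi_i - phi_j)`, and bilinearly resized to
224 × 224. Two points deserve emphasis:

* The cosine form is symmetric with a unit diagonal. The classical
  "difference field" uses `sin(phi_i - phi_j)`; the cosine form is the
  package default because it is the form the reference prints, and the sine
  variant is available as `gadf_config(variant = "sin")`.
* `cos(phi_i - phi_j)` expands to `cos phi_i cos phi_j + sin phi_i sin
  phi_j`, so G has rank 2 and bilinear resizing (separable and linear)
  commutes with the outer products. For long series the package therefore
  interpolates the two vectors and forms the outer products at the target
  resolution — an algebraic identity with the materialize-then-resize
  composition (tested to machine precision), not an approximation. The
  `fast_path` option is different: it piecewise-aggregate downsamples the
  series *before* the transform, which is approximate; a regression test
  freezes its deviation on a slow sinusoid at < 0.1.
* Resizing uses the align-corners convention (endpoints map to endpoints),
  so resizing to the input size is exactly the identity and every output
  pixel is a convex combination of inputs.

The image encoder is a bottleneck residual network (depths 50/101/152, all
emitting 2048 features after global average pooling, classification layer
removed; default depth 101). Grayscale pixels are mapped affinely from
[−1, 1] to [0, 1], replicated to three channels, and normalized with the
standard pretrained-backbone channel statistics (configurable). Pretrained
weights are loaded from a local checkpoint when one is supplied; otherwise
initialization is random — the package never downloads. Batch normalization
is folded to its inference-mode per-channel affine form (learnable scale and
shift; running statistics are identity at random initialization and absorbed
into the affine when weights are loaded): the package's training regime
processes records individually, where batch statistics would be degenerate.
With `fine_tune = "partial"` only the two deepest residual stages receive
gradients and optimizer updates.

Because a full-depth residual network cannot be *trained* within a
single-CPU test budget, the package also provides a `"tiny"` backbone (a
two-layer perceptron over the downsampled image). It is an explicitly
labelled engineering surrogate used by the training tests; the faithful
backbone is exercised forward and backward at reference resolution in its
own tests.

**Metadata.** Age, gravidity and parity are z-scored with means and sample
(n−1) standard deviations computed on the *training split only*; missing
values (gravidity is occasionally missing in real cohorts, ~0.7%) are
imputed with the training mean before standardization, hence standardize to
zero. The binary gestational-diabetes indicator passes through unchanged.
The autoencoder is 4 → 64 (ReLU) → 32 on the way in and the mirror image on
the way out; only the 32-dimensional latent feeds fusion, while the
reconstruction is a training-time regularizer that keeps the metadata branch
from collapsing when stronger modalities dominate.

Two different standard-deviation conventions coexist deliberately:
population (÷n) for instance normalization — a per-record operation where
the signal *is* the population — and sample (÷(n−1)) for metadata statistics
estimated from a finite training split.

## Fusion and the objective

The three feature vectors are linearly projected into a shared
`d_common = 128` space, stacked in the fixed order (signal, image,
metadata), and offset by a learnable modality embedding. The fusion encoder
runs `n_layers = 2` *post-norm* residual blocks with `n_heads = 4`:
LayerNorm is applied to each residual sum, exactly as the reference
formulates it, even though pre-norm is the more common modern default — the
package reproduces the stated algebra, and the oracle test checks the block
against a hand-rolled plain-matrix reference. Mean pooling over the three
tokens and a linear head give two logits.

The reference states a scalar sigmoid head in one place and a softmax over C
classes with label smoothing in its loss; these are irreconcilable as
printed. The package implements the two-logit softmax head, which matches
the loss definition and has the same decision geometry as the sigmoid form.

The objective is `L = L_cls + lambda * L_rec` with `lambda = 0.5`:
label-smoothing cross entropy (`epsilon = 0.1`, so targets are
`[0.1, 0.9]` for an abnormal record) plus the mean per-sample squared
metadata-reconstruction error. At inference the reconstruction pathway is
skipped entirely.

Ablation switches mirror the reference protocol: modality masking (a masked
modality's token is *omitted*, never zero-filled, so attention never sees a
fake token and the masked encoder is not even instantiated), FHR-only versus
FHR+UC channels, and concat / add / MLP fusion baselines (classifier width
`3d` under concat).

## Training protocol

Adam (learning rate 1e-3, weight decay 1e-4 folded into the gradient as in
mainstream frameworks, batch 64, up to 100 epochs), with the best-validation
checkpoint retained. The validation selection metric defaults to QI — the
headline balanced metric — configurable to AUC or loss. Splits are
stratified 6:2:2 with per-class floor/floor/remainder rounding, the unique
convention that reproduces the canonical 552-record cohort sizes 331/110/111
with per-class counts (198,133)/(66,44)/(66,45). Each seed (defaults 0, 42,
3407) gets its own split, training run and evaluation; results are reported
as mean ± sample sd. No learning-rate schedule and no class re-weighting are
used (none are stated in the reference protocol; label smoothing is the only
imbalance mitigation). All of this runs on the package's reverse-mode
autodiff engine, whose gradients are verified against central finite
differences through every operation, including the convolutions.

## Metrics

Confusion-based metrics at a 0.5 threshold on the abnormal probability (the
reference never states its operating threshold): ACC, SEN, SPE,
QI = √(SEN·SPE), F1 = 2TP/(2TP+FP+FN), MCC. Zero denominators yield 0 for
SEN/SPE/F1 and MCC. AUC is computed twice — trapezoidal area under the
threshold-swept ROC with tied scores grouped, and the tie-corrected
Mann–Whitney rank statistic — and the two are cross-checked on every call.
The Brier score is the mean squared difference between predicted
probabilities and outcomes.

## The synthetic world

The generator emulates exactly the structure the model assumes: FHR as a
per-record baseline (≈140 ± 10 bpm) plus sinusoidal and band-limited
variability (≈5 bpm); UC as periodic Gaussian contraction bumps (default
every 180 s) on a low baseline; the abnormal class adds Gaussian
decelerations of configurable depth lagged 30 s behind contraction peaks —
late decelerations by construction; artifacts (out-of-range dropouts, +40
bpm spikes, ±35 bpm jumps, UC spikes) injected with ground-truth masks; and
label-coupled metadata (higher diabetes prevalence and mean age in the
abnormal class, with gravidity missing at 0.7%). Default class prevalence is
60% abnormal, mirroring the screened clinical cohort.

What it does **not** emulate: FIGO-style morphology (accelerations,
variability classes, sinusoidal patterns), gestational-age effects, device
noise spectra, inter-observer label noise, or the clinical screening funnel
that produces a real cohort. A green training test on this world therefore
establishes that the architecture, gradients, protocol and bookkeeping are
correct and that the model can extract planted signal — it says nothing
about clinical performance, which is why the package reproduces the
reference *protocol* but not its headline numbers.

One qualitative claim did not transfer: on real data, abnormal GADF images
are described as showing stronger structured texture. On this generator the
*normal* class shows the higher fine-scale contrast, because min–max
rescaling lets a deep deceleration stretch the value range and compress the
ordinary variability band. The texture statistic still separates the classes
cleanly — the direction is simply generator-specific, and the test asserts
the measured direction with a comment to that effect.

## Numerical choices and degenerate inputs

* Constant series rescale to the GADF interval midpoint rather than
  erroring.
* `acos` inputs are clamped within a 1e-8 tolerance; larger excursions are
  domain errors. Gramian entries are clamped to [−1, 1] to absorb sub-ulp
  floating-point overshoot of the analytic range.
* Instance normalization guards variance with `eps = 1e-5`; zero-variance
  metadata fields guard their sd to 1 with a warning.
* Checkpoint selection keeps the *first* epoch achieving the best validation
  metric (strict improvement), making selection deterministic under ties.
* Stratified splitting requires at least 3 members per class; training
  requires both classes in train and validation splits.
* Divergence (non-finite loss) aborts training with a diagnostic rather
  than silently continuing.
* Seeded operations snapshot and restore the caller's RNG state.

## Scale-down policy for tests

Training-based tests shrink the segment length (480–600 samples), model
width (`d_model = 32`, one signal layer) and image size (16 × 16 tiny
backbone) to fit a single CPU, and say so where they do. Architecture,
losses, protocol and seeds are never changed; thresholds derive from the
stated acceptance criteria, and regression tolerances were frozen at their
first measured values.

## Known limitations

* The faithful residual backbone is practical for forward passes and
  gradient checks on CPU, not for full-scale training; training the image
  branch at reference scale requires the surrogate backbone or porting the
  weights.
* The WFDB reader supports the two-channel format-16 layout used by the
  public intrapartum database, not the full WFDB zoo; maternal header
  field names are mapped through a configurable alias table whose defaults
  should be checked against a concrete database export.
* Dropout regularization uses one shared rate; per-sublayer rates are not
  exposed.
* No calibration post-processing (the Brier score is reported, not
  optimized directly beyond what label smoothing provides).
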