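---
title: "FECC-Net in R: model, design choices and what the synthetic experiments show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FECC-Net in R: model, design choices and what the synthetic experiments show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(feccnet)
```

## The model

`feccnet` segments hypo-intense chronic-stroke lesions in axial T1 MRI
slices with a binary encoder–decoder network. The architecture has four
ingredients, each aimed at a failure mode of plain U-Nets on lesion data.

**Main encoder.** Four levels; each applies two 3×3 convolutions (batch
normalization + ReLU) and a squeeze-and-excitation (SE) block, then 2×2 max
pooling. SE pools each channel to a scalar, passes the vector through a
two-layer bottleneck (reduction 8) and rescales channels by sigmoid gates in
(0, 1) — cheap channel attention that suppresses redundant features.
Convolutions immediately followed by batch normalization carry no bias; the
normalization shift makes one redundant, which matters when calibrating
parameter counts.

**ASPP bottleneck.** At 1/16 resolution, parallel 3×3 convolutions at
dilation rates {1, 6, 12, 18} (the DeepLab-v3 convention) run side by side,
are concatenated, and fused by a 1×1 conv block. A 3-tap dilated kernel at
rate *d* spans 2*d*+1 pixels per axis, so the branch ensemble sees context
from 3 to 37 pixels wide at no resolution cost. We include no image-level
pooling branch: it buys little on single-slice input and costs parameters.

**Enhanced encoder.** A second encoder over the raw slice: a stem of two
conv blocks at full resolution, then per level a stack of three
depthwise-separable blocks (depthwise 3×3 + pointwise 1×1, each with batch
norm + ReLU) followed by pooling. It emits one feature map per level, at
resolution `input_size / 2^l`. The factorized convolutions are
parameter-cheap (k²·C + C·C′ versus k²·C·C′), which lets this branch stay
deep and wide enough to preserve shallow boundary detail without blowing the
budget.

**Decoder and head.** Each decoder level upsamples 2× bilinearly (a
parameter-free choice, deliberately cheaper than transposed convolution),
applies a conv block, concatenates the main-encoder skip at that resolution
and — in the full variant — the enhanced-encoder map of the level below
upsampled 2×, then applies two conv blocks. A 1×1 convolution with bias and
a logistic activation produces the per-pixel lesion probability, binarized
at 0.5. The secondary-skip geometry (enhanced map taken *after* pooling,
upsampled back before concatenation) is our reading of the design; the
alternative (pre-pooling maps, like the main skips) differs only in where
the halving happens and was not pursued.

## The hybrid loss

Training minimises `HL = sqrt(L_BCE² + L_Dice²)` where BCE is mean-reduced
over the flattened pixel set of the batch and Dice is computed over the same
set, smoothed by `delta`:

* BCE keeps per-pixel probabilities calibrated and prevents the all-background
  collapse early in training;
* Dice directly optimises overlap and counteracts foreground/background
  imbalance (lesions are often < 1 % of a slice);
* the L2 coupling weights whichever component is currently larger, so
  neither gradient vanishes; `HL ≥ max(components)` and `≤` their sum.

Numerical guards: probabilities are clamped to `[1e-7, 1 - 1e-7]` before
logarithms; `delta` defaults to 1e-15 and anything in [1e-15, 1e-13] changes
the loss by < 1e-10 on any non-empty mask (tested). A focal-loss baseline
(γ = 2, α = 0.25, the convention of its original description) is included
for loss-ablation runs via `compare_losses()`.

## Parameter budgets and the calibration procedure

The channel schedule is not dictated by the architecture, so it is a
calibration surface. The procedure, run once with the package's own
`count_parameters()` (which sums kernels, biases, batch-norm scale/shift and
SE dense layers — exactly the trainable scalars):

1. fix the encoder schedule shape at a doubling ladder `(C, 2C, 4C, 8C)`;
2. with the enhanced encoder off, scan the base width and ASPP width until
   the lite variant rounds to 3.8 M — landing on schedule (24, 48, 96, 192)
   with 168 ASPP channels (3,780,598 parameters);
3. with the lite side frozen, scan the enhanced-encoder widths and stack
   depth until the full variant rounds to 7.0 M — landing on enhanced
   widths (64, 128, 256, 760) with three stacked depthwise-separable blocks
   per level (7,013,398 parameters).

The budget gap between the variants is carried partly by the enhanced
encoder itself and partly by the wider decoder concatenations it induces;
hitting both printed budgets forces the enhanced branch to be substantially
wider than the main encoder, which the depthwise factorization makes
affordable. The frozen configuration is the package default
(`fecc_config()`).

## Implementation notes

No R deep-learning framework exists in this package's dependency footprint,
so the network engine is implemented here on base-R matrix algebra:
convolutions are im2col gathers (cached integer index matrices per tensor
shape) followed by one BLAS GEMM; conv→BN→ReLU and depthwise→BN→ReLU are
fused so normalization and activation run on the GEMM output matrix
directly; gradients flow through an explicit reverse pass over the static
graph. The backward pass of every layer family is verified against central
finite differences (relative tolerance 1e-4) in the test suite, which is the
strongest correctness oracle available for an autodiff engine. Adam uses
standard β₁ = 0.9, β₂ = 0.999, ε = 1e-8; batch-norm ε = 1e-3, momentum 0.1;
He-uniform initialization, fully seeded — two builds from the same config
and seed are bit-identical, and so are two training runs.

Other numerical conventions: size-preserving zero padding everywhere
(stride 1); bilinear upsampling uses half-pixel centres with replicated
edges; max-pool ties break toward the first element in scan order;
metric conventions `0/0 = 1` (an empty prediction of an empty truth is
perfect) with lesion-free slices excluded from stratified metric rows
anyway; stratum boundaries are half-open, `[1,100)`, `[100,1000)`,
`[1000, ∞)`, resolving the ambiguity at exactly 100/1000 pixels toward the
larger class.

## The synthetic data generator

`generate_slice()` emulates the *structure* of the segmentation problem: a
bright elliptical "brain" (axes 0.40–0.46 of the image side) with a smooth
low-frequency intensity texture plus per-pixel noise on a dark background,
and 1–3 hypo-intense lesion blobs grown from random-walk seeds, dilated ring
by ring with the final ring subsampled so the total foreground count lands
exactly in the requested stratum interval. Lesion intensity is the local
smoothed tissue value minus `lesion_intensity_drop` (default 60 on the
[0, 255] scale) ± a jitter bounded by a quarter of the drop, so every lesion
pixel is at least half the drop darker than its local background — a
guaranteed learnable contrast. Blob shapes are deliberately irregular so
boundary recovery is non-trivially exercised.

What it does **not** emulate: anatomy (ventricles, cortex, skull), MRI
physics (bias fields, partial-volume effects), inter-case intensity
variation, or 3D continuity between slices. Passing the synthetic smoke test
therefore demonstrates that the architecture, losses, gradients, training
loop and evaluation machinery work end to end and that the network can learn
contrast-plus-shape segmentation from scratch — it says nothing about
accuracy on real MRI, which requires the real dataset and GPU-scale
training.

## Study sizes used by the test suite

The suite trains the reduced-width profile (`fecc_test_config()`: 64×64
slices, schedule 8–32, ASPP rates {1, 2, 4} matched to the 4×4 bottleneck)
on 200 synthetic slices (40 % lesion-free, 20 % per lesion stratum, seeded),
split 8:1:1 by pseudo-case, for 18 epochs at learning rate 2e-3 with batch
size 16 — sizes chosen so a plain CPU finishes in minutes while leaving a
clear margin over the held-out DSC 0.8 sanity bar (typical result ≈ 0.9).
The 512-scale profile keeps the printed protocol defaults (Adam, learning
rate 1e-4, batch 16, up to 300 epochs with early stopping on validation
DSC, patience 20); the larger rate at desk scale simply reflects the much
smaller network and easier task. The noise experiment corrupts 120 fresh
slices with σ = 40 Gaussian noise and asserts the qualitative robustness
ordering: every stratum degrades at most marginally upward (+0.02
tolerance), and the small-lesion stratum degrades most — small targets
depend most on local contrast, which noise destroys first.

## Known limitations

* CPU training at 512×512 with the 7.0 M-parameter configuration is
  possible but slow; the package is honest experiment machinery, not a
  production inference engine.
* Batch-norm evaluation statistics converge over a few epochs; very short
  runs evaluate with partially warmed running statistics.
* The NIfTI path assumes the axial axis is the third array axis as stored
  and applies volume-level min–max intensity rescaling; data with unusual
  orientations should be reoriented upstream.
* Checkpoints are R serializations plus a JSON config sidecar; they are not
  interchangeable with other frameworks.
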