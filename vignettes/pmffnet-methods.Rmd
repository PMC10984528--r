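---
title: "Segmenting ovarian-tumor ultrasound with pmffnet: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting ovarian-tumor ultrasound with pmffnet: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmffnet)
```

## The problem and the model

Ovarian lesions in 2-D ultrasound are hypoechoic regions with diffuse,
speckle-corrupted boundaries. `pmffnet` implements PMFFNet, an
encoder–decoder network for the binary task (lesion vs background):

* **Encoder (V2S).** A four-stage hybrid CNN–transformer pyramid. Each stage
  opens with a *reduction cell* (RC) that downsamples by 4×, 2×, 2×, 2× using
  three parallel strided convolutions at dilations 1/2/3 (a locality bias)
  followed by a 1×1 embedding, and continues with *normal cells* (NC) that mix
  tokens with window attention, a parallel 3×3 convolution path, and a GELU
  feed-forward, all in pre-norm residual form. The pyramid is tapped after
  each stage's last NC, at strides 4/8/16/32 (a 384×384 input yields
  96/48/24/12 sides).
* **Varied-size window attention (VSA).** Queries attend within default 7×7
  windows; a per-window regression head (average pool → two-layer MLP)
  predicts a per-head scale and offset, and keys/values are resampled
  bilinearly from the transformed windows. The scale is parameterized through
  an exponential and the final regression layer is zero-initialized, so at
  initialization VSA is *exactly* fixed-window attention — a property the
  test suite checks to 1e-5.
* **MFB.** At every scale a multi-scale feature fusion block runs two
  branches in parallel: an expanded-receptive-field branch (ERF: two dilated
  blocks, each three conv blocks at dilations 1, 2, 5 → a hole-free 33×33
  receptive field) and a local-emphasis branch (LE: four plain 3×3 convs →
  9×9), concatenates them and fuses with two residual blocks down to 64
  channels.
* **Decoder.** Starting from the deepest MFB output, each fusion step
  upsamples by exactly 2×, concatenates the next-shallower MFB map (64 + 64 =
  128 channels) and applies RB(128→64), RB(64→64); after the 1/4-scale step
  the map is upsampled to input resolution and a head of two RBs plus a 1×1
  convolution emits one logit per pixel.

Training minimizes the compound loss `BCE + Dice` (Dice smoothed with 1 so a
doubly-empty mask costs nothing), with AdamW at an initial learning rate of
1e-4, batch size 8, 100 epochs, halving the learning rate whenever
validation mDice stagnates for 10 consecutive epochs, and keeping the
checkpoint with the best validation mDice.

## The dilation calculus

Stacked dilated convolutions can leave input pixels unused (the gridding
effect). For a cascade with kernel K and dilations `d_1..d_Z` the maximum
distance between adjacent nonzero taps follows the top-down recursion

```
M_Z = d_Z,    M_i = max(M_{i+1} - 2 d_i,  2 d_i - M_{i+1},  d_i)
```

and the design goals are `M_2 <= K` and `M_1 = 1`. For K = 3 and dilations
(1, 2, 5): `M_2 = max(1, -1, 2) = 2 <= 3`, so the schedule is sound:

```{r hdc}
sched <- dilation_schedule(c(1, 2, 5))
hdc_max_distances(sched)
receptive_field(sched)
count_holes(usage_count_map(sched))
count_holes(usage_count_map(dilation_schedule(c(2, 2, 2))))
```

The package also carries a brute-force oracle (`usage_count_map()`) that
back-propagates tap counts from one output pixel on an unbounded canvas.
Exhaustive enumeration over all cascades with Z ≤ 3, K = 3, d ≤ 6 shows the
criterion is *sufficient* for hole-free coverage but not *necessary*: a
sparse bottom layer followed by a dense one (dilations 2 then 1) covers the
footprint even though `M_1 = 3`. The test suite therefore pins the one-sided
implication, with the oracle as the authority; the canonical examples
(1, 2, 5) hole-free and (2, 2, 2) gridded behave exactly as expected.

## Design choices the architecture description leaves open

These points are not fixed by the published description; the package makes
one choice each and exposes it in configuration:

* **Stage widths and depths.** Only the encoder family name and a total of
  "23 M" parameters are public. Defaults: widths (64, 64, 192, 448), NC
  depths (2, 2, 8, 2), heads (1, 2, 4, 8), FFN ratio 4, MFB width 64 —
  22.87 M trainable scalars, which rounds to 23 M. All of it is
  `pmffnet_config()` input.
* **MFB channel plan.** Branch widths are not stated; the decoder's stated
  RB(128→64) after concatenating an upsampled map with a skip forces 64
  channels per MFB output, so each branch projects its backbone input to 64
  at its first conv block and fusion concatenates 64‖64 → 128 → 64 × 64.
  Concatenation (not addition) is chosen so the first fusion RB naturally has
  a 128-channel input, mirroring the decoder's pattern.
* **Group count.** Group normalization is cited without a group count; 8 is
  used wherever it divides the width (1 otherwise).
* **Residual projection.** A learned 1×1 convolution aligns channels when a
  block changes width; residual addition is undefined otherwise.
* **Upsampling.** Bilinear, half-pixel centers, parameter-free; expressed as
  two interpolation matrices whose transposes give the exact adjoint for the
  backward pass.
* **Position bias under varied windows.** The relative-position table lives
  on the integer offset grid; for fractional sampled offsets it is read
  bilinearly. The offsets are treated as constants in the backward pass
  (gradients reach the regression head through the resampled keys/values,
  not through the bias), which keeps the identity-initialization equivalence
  exact and the implementation simple.
* **Padding semantics.** Feature sides not divisible by the window are
  zero-padded bottom/right; padded tokens participate in attention and the
  output is cropped. No attention masking is applied — the padded keys carry
  zeros and the model learns around them.
* **Initialization.** Truncated normal (sd 0.02) for linear maps, fan-in
  scaled (He) normal for convolutions, normalization affine at identity,
  zero for the window-regression output. Fan-in rather than fan-out scaling
  matters for the 1-channel prediction head: fan-out would scale its 1×1
  kernel by `sqrt(2)`, exploding the initial logits.
* **Plateau semantics.** "Improvement" is strictly greater validation mDice
  than the best so far (min-delta 0); the stagnation counter resets on a
  drop event.
* **Dice at evaluation.** The smoothed form (smooth 1) is the default, as in
  the published metric; `metrics_from_counts(..., smooth = 0)` recovers the
  raw ratio, and the identity `Dice = 2 IoU / (1 + IoU)` is tested in that
  limit. Training uses soft (probability) intersections; evaluation uses
  binarized masks.
* **Zero-denominator convention.** For images where ground truth and
  prediction are both empty, IoU/precision/recall are 1 (the prediction is
  perfect); if exactly one side is empty they are 0.
* **Accuracy denominator.** The printed accuracy formula repeats TN where FN
  belongs; the implementation uses the standard
  `(TP + TN) / (TP + TN + FP + FN)`, which is what the accompanying prose
  describes.

## The synthetic phantoms

Real MMOTU-style archives cannot ship with the package, so every pipeline
stage is exercised on seeded synthetic speckle phantoms
(`generate_phantom()`): a smooth low-frequency background field multiplied
by unit-mean gamma speckle (shape 4, a standard ultrasound speckle
surrogate), exactly one hypoechoic lesion per image — an ellipse with a
sinusoidally perturbed, softly blurred boundary, 45% as bright as its
surroundings by default — and the exact interior as the binary mask. Image
sides vary per phantom so the resize path is always exercised; a
`shifted` corpus variant (weaker contrast, stronger speckle) emulates a
generalization set from a different acquisition protocol.

What the phantoms do *not* emulate: acoustic shadowing and enhancement,
multiple or contiguous lesions, anisotropic speckle, Doppler overlays,
annotation noise. Tests passing on phantoms therefore validate the
machinery — shapes, gradients, losses, the training protocol — not clinical
performance; the published test-set figures require the real archive and
GPU-scale training and are out of scope here.

## Numerical engine and problem sizes

No deep-learning framework is available to R in this stack, so the package
carries its own reverse-mode autodiff engine: dense arrays in
(H, W, C, N) layout, convolutions via im2col + GEMM in compiled code,
gradients for every op checked against central differences in the test
suite. Determinism: all randomness flows through R's RNG; a model seed,
data seed and training seed reproduce runs bit-for-bit in evaluation mode.

The test suite sizes its runs for a single CPU: gradient checks on toy
tensors, the full-resolution (384×384) forward pass once, and an
overfit-capacity run — 8 phantoms at 96×96, 200 AdamW steps at learning
rate 1e-3 on the reduced `pmffnet_config_small()` configuration — which
reaches training mDice ≥ 0.95 with a wide margin (typically ≥ 0.98). The
overfit run checks the training loop's correctness, not the default
architecture's capacity, hence the reduced widths.

## Known limitations

* CPU-only and R-level: full-resolution inference takes tens of seconds per
  image; training the 23 M-parameter default at 384×384 is impractical here.
  The architecture is faithful; the published headline metrics are not
  reproducible at this scale.
* Binary segmentation only; the eight tumor categories are out of scope.
* `ImageNet` pretraining of the encoder is not performed;
  `load_checkpoint()` accepts externally supplied weights in the package's
  own format only.
* Attention treats bottom/right padding tokens as ordinary zeros rather than
  masking them; for sides well below the 7-pixel window this blunts the
  attention pattern (the deepest stage of a 96-pixel input is 3×3, padded to
  7×7).
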