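---
title: "Multiscale visual state-space segmentation: model, design decisions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale visual state-space segmentation: model, design decisions, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vssunet)
```

## The model

The package implements a U-shaped encoder–decoder for pixel-wise pest
segmentation whose basic operator is the two-dimensional selective scan
(SS2D). An `H × W × D` feature map is unrolled along four traversal
orders — row-major from the top-left, its reversal, column-major from
the top-right, and its reversal — and each sequence passes through a
causal first-order state-space recurrence with input-dependent gates
(the "S6" selective scan):

$$h_t = e^{\Delta_t A}\,h_{t-1} + \Delta_t B(x_t)\,x_t,\qquad
  y_t = C(x_t)\,h_t + D \odot x_t,$$

with $\Delta_t = \mathrm{softplus}(W_\Delta x_t + b_\Delta) > 0$ and
$A \le 0$ per (channel, state), so the discretized transition
$e^{\Delta_t A}$ lies in $(0,1]$. The four outputs are re-laid onto the
grid and summed. Each position therefore aggregates information from
the whole image at a cost linear in the pixel count, which is the
architecture's selling point against quadratic self-attention.

The network composes this operator into:

* **VSS block**: LN → linear expansion (ratio 2) → depthwise 3×3 conv →
  SiLU → SS2D → LN, multiplied elementwise by a SiLU-gated side path
  computed from the *same* first LN, then projected back and added to
  the input.
* **MSVSS**: VSS followed by LN, a four-branch parallel convolution
  stage with kernels 1/3/5/7 (summed), and a linear projection.
* **CSA**: channel attention (shared two-layer MLP on global average-
  and max-pooled descriptors, sigmoid gate) followed by spatial
  attention (channelwise average/max maps, 7×7 conv, sigmoid gate).
* **IAF skip**: encoder and decoder features pass through CSA and 1×1
  projections; their ReLU'd sum drives a 1×1 conv + sigmoid gate that
  multiplies the *encoder* features. The gated encoder features are
  added to the decoder stream.
* **AVSS bottleneck**: a VSS block whose LN+3×3-conv refinement is
  gated by a sigmoid of channelwise average+max pooled maps and added
  back to the VSS output.
* **IPM / IPE**: learned downsampling (1×1 conv doubling channels, then
  a stride-2 depthwise-separable 3×3, then 1×1) and its mirror
  (1×1 halving channels, transposed 3×3 stride 2, 1×1, LN).

A 4×4 patch embedding (default width `C = 96`) precedes four encoder
stages of two MSVSS blocks each, with IPM between consecutive stages
(channel schedule C, 2C, 4C, 8C; bottleneck at 1/32 resolution); the
decoder mirrors the encoder with IPE and IAF skips, and a final
patch-expanding projection (linear to `p²·C` channels, pixel shuffle,
LN, linear head) restores full resolution.

Training minimizes the hybrid loss
$\sigma\,L_{CE} + (1-\sigma)\,L_{Dice}$ with $\sigma = 0.6$ by default
($\sigma = 1$ recovers plain cross-entropy), with SGD at constant
learning rate $10^{-4}$, batch size 15, momentum 0.5, weight decay
$10^{-5}$, under 5-fold cross-validation.

## Design decisions where the architecture description is open

Several details are not fixed by the block equations alone; the package
resolves them as follows and exposes switches where both readings are
defensible.

* **Traversal orders.** Only the endpoints of the four scans are named.
  We fix: top-left→bottom-right = row-major; top-right→bottom-left =
  column-major taking columns right-to-left; the other two are their
  exact reversals. Any fixed bijection satisfies the endpoints; these
  match the row/column forward/backward convention of published 2D
  selective scans.
* **S6 parameterization.** The internal parameters of the selective
  scan are unnamed in the block equations; we use the established
  selective-scan form (nonpositive transition stored as `−exp(A_log)`,
  softplus step size, linear input/output gates, per-channel
  feedthrough, state size 16 by default). Per-direction parameters are
  independent, with a shared-weights switch.
* **Merge reduction** is a sum (not a mean); downstream LayerNorm
  absorbs the factor 4.
* **Gate path of the VSS block.** The printed composition applies the
  same LN to both the main and the gate path (`Lin3(LN1(·))`), so LN1
  is shared; `Lin3` is its own projection.
* **MSVSS outer residual.** Read literally, the MSVSS composition has
  no outer residual — only VSS carries `+ input`. The block implements
  the literal reading by default (`outer_residual = FALSE`); with
  0.02-sd initialization this multiplies the signal by a small random
  projection at every block, so deep encoders attenuate input
  information. The desk-scale training configuration
  (`desk_config()`) therefore enables the outer residual; the flag, not
  the equations, decides.
* **Multiscale branches.** The equation prints kernels 1/3/5/7; the
  prose says "dilated". Default follows the equation; a
  `msdc_dilated` switch provides kernel-3 branches at dilations 1/2/3
  (same receptive fields). Branch combination is elementwise sum, with
  a concat-project variant behind `msdc_combine`.
* **IAF gate width.** The 1×1 gate convolution's output width is
  unstated; we use one channel broadcast over channels, the
  attention-gate convention. The fused output is *added* to the decoder
  stream at the same resolution (after IPE).
* **AVSS pooling** is channelwise (producing an `H × W` spatial gate),
  mirroring the CSA spatial path; global pooling would duplicate the
  channel gate CSA already provides.
* **IPM/IPE factors.** Spatial ÷2 with channels ×2 (and the inverse),
  the standard U-shaped doubling; the two are forced to be shape-
  inverse. Between-stage placement gives three IPMs for four stages,
  so the printed 4× final projection restores full resolution.
* **Padding** is zero 'same' everywhere (shape preservation is required
  by the residual adds); the spatial-attention conv can use replicate
  borders via `csa_spatial_padding`, under which a spatially constant
  input provably yields a spatially constant gate.
* **Initialization**: truncated normal (sd 0.02) for linear/conv
  weights, ones/zeros for norms, a real-S4D ladder for the scan
  transition, step-size bias drawn so softplus lands in
  [0.001, 0.1]; all fixed by `cfg$seed`. ImageNet pre-training is out
  of scope; weights are random.
* **Empty-class conventions**: probabilities clamped at 1e-7 inside
  logs; Dice smoothed by `smooth_eps = 1` (empty vs empty is perfect
  overlap); undefined metric ratios (0/0) report 100%. Entropy uses
  log base 2 (bits); the median split is base-invariant. Ties at the
  entropy median go to "low". Argmax ties (class prediction, max-pool
  routing) break toward the first index.

## Synthetic data: what it emulates, what it does not

The generator stands in for field pest imagery with known ground truth.
Pests are perturbed ellipses (random aspect 1.1–2.2, low-order radial
Fourier perturbation) with a size-scaled budget of appendage strokes;
the realized mask area is calibrated within ±20% of the target (with a
2-pixel floor so tiny pests remain drawable). Backgrounds come in three
complexity levels — smooth (gradient), textured (band-limited noise),
cluttered (leaf-like strokes plus broadband noise) — which are
statistically ordered in 256-bin entropy, so an entropy median split
separates them. Foreground color is a convex mix of the local
background mean and a pest palette with weight `contrast` (default 0.4,
a deliberately low-contrast regime); `occlusion_fraction` (default 0.2)
draws a foliage-colored strip across a pest and relabels covered pixels
as background. Dataset size and stratum mix are parameters, not
constants; generation is a pure function of `(n, mix, seed)`.

What passing tests on these scenes shows: the implementation learns,
the losses/metrics/stratification bookkeeping is exact, and shapes and
gradients are correct. What it does not show: performance on real
imagery — the generator has no life stages, no camera blur/exposure
variation beyond the augmentation protocol, no 102-class taxonomy, no
long-tail census, and blob texture is far simpler than insect texture.

## Problem sizes and numerics

CPU-scale runs use `desk_config()`: embedding width 16, two stages of
two blocks, scan state size 8, 64×64 inputs — chosen so a full
300-iteration, 8-image training run finishes in minutes on one core.
Unit tests run on grids up to 8×8 with 2–4 channels, where the
brute-force recurrence oracle is exact and fast. The SS2D oracle
comparison uses a relative tolerance of 1e-5 (double-precision
accumulation over ≤ 10³ steps is far tighter; the margin covers the
softplus/exp evaluation-order differences between implementation and
oracle). Backward passes are validated against central finite
differences at 1e-5 (shrunk to ~3e-7 where a max-pool argmax flip sits
inside the perturbation window — the loss is continuous but only
piecewise smooth, so the central difference across the kink is biased
at larger windows).

## Known limitations

* **The published optimization regime cannot overfit from random
  initialization.** With mean-reduced cross-entropy, a [0,1]-bounded
  Dice term, and constant lr 1e-4 (momentum 0.5), per-iteration
  parameter movement from a randomly initialized model is of order
  1e-5; 300 iterations move the loss by well under 0.1 and leave
  training DSC near zero. The capacity check in the acceptance suite
  runs exactly these settings and documents the observed value rather
  than weakening the bar. Diagnostics at 100× the learning rate show
  fast loss descent followed by collapse to the majority (background)
  class — the standard class-imbalance stall, where the softmax
  saturates and the Dice gradient vanishes. The published protocol
  avoids this regime by starting from ImageNet-pretrained weights
  (explicitly out of scope here) and training on thousands of images.
* The sequential recurrence is the authoritative implementation; no
  parallel prefix-scan kernel is provided, so wall-clock speed is not
  representative of GPU implementations of the same architecture.
* The final 4× patch-expanding head predicts sub-patch detail only
  through channel mixing (pixel shuffle), so very fine boundaries are
  harder to fit than with a convolutional decoder at full resolution.
* Evaluation aggregates per-image metrics by unweighted means within
  strata; fold dispersion is reported as the standard deviation of
  fold means, not a bootstrap interval.
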