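---
title: "Frequency-domain dual-branch fusion for histopathology classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-domain dual-branch fusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affnet)
```

## The problem and the model

Hematoxylin–eosin (H&E) histopathology images of breast lesions carry much
of their diagnostic signal in *periodic texture*: nuclear packing, gland
architecture and stromal patterns show up as energy concentrated at
characteristic spatial frequencies. `affnet` implements a dual-branch
network that exploits this directly. A shared stem (4×4 stride-4
convolution + layer norm) reduces a 224×224 RGB input to a 56×56 feature
map; four stages then follow, each holding two branches that both consume
the stage input:

* a **convolutional branch** of ConvNeXt-style blocks (7×7 depthwise
  convolution, layer norm, 4× inverted bottleneck with GELU, layer scale,
  residual), each block gated by **multi-spectral channel attention
  (MSCA)**;
* a **transformer branch** of Swin-style blocks (window attention with
  relative position bias, alternating shifted windows, 4× MLP), each block
  gated by the **Fourier filtering enhancement operator (FFEO)**.

The branch outputs `L_i` (local) and `G_i` (global) are fused per stage by
**adaptive frequency-domain fusion (AFDF)**, and a single strided
convolution carries the fused map to the next stage, doubling channels
(128→1024 in the reference configuration) and halving resolution
(56→7). A pooled, layer-normalised linear head produces the class logits
(8 classes for the BreaKHis subtypes, 4 for BACH-style data).

### MSCA

The `C` channels of a map are divided into `n = 16` parts; part `i` is
summarised by projecting each of its channels onto a single orthonormal
2-D DCT atom. The `n` selected frequencies are the 16 lowest `(u, v)`
pairs of a 7×7 DCT plane in zigzag order, rescaled to the stage
resolution — a low-frequency-first choice, since the DCT concentrates
natural-image energy in its low-frequency coefficients. The concatenated
length-`C` frequency descriptor passes through a squeeze–excitation
bottleneck (reduction `r = 16`, ReLU). `msca_forward()` returns
*pre-sigmoid* logits and the enclosing block applies
`sigmoid(·) ⊙ feature-map`, so gating happens exactly once — the
alternative reading (a second multiply inside the attention module itself)
would gate twice, and nothing in the model needs it.

The DCT normalisation is orthonormal (`c(0) = sqrt(1/L)`,
`c(k>0) = sqrt(2/L)`): atoms then have unit energy and projections onto
different frequencies are comparable, which is what a cross-part channel
descriptor requires.

### FFEO

The map is transformed with a real 2-D FFT to the Hermitian half-plane
`H × (W/2 + 1)`. Bins are sorted by the radial key
`r(u, v) = sqrt(min(u, H−u)² + v²)` (Hermitian-aware in the row direction,
ties row-major) and split into equal low-pass and high-pass halves —
`½·H·(W/2+1)` bins each; with an odd bin count the low-pass side receives
the extra bin (at the reference resolutions all stage bin counts are
even, so the rule only matters for unusual configurations). Each band is
filtered by its own two-layer complex MLP whose weights are
block-diagonal — `N = 4` independent `(C/N)×(C/N)` blocks shared by all
bins of the band, ReLU applied to real and imaginary parts independently —
followed by the enhancement step

`z' = α · softshrink(z, λ) + (1 − α) · (z − softshrink(z, λ))`,

an inverse FFT and a residual connection. With the operating value
`α = 0.5` the enhancement step is *algebraically* `0.5 · z` for every
λ — the soft-shrink contribution cancels. The operator is implemented
exactly as written, the collapse is asserted by a test, and λ (`0.01`,
not learned) is kept because the same code path serves ablations with
other α where the threshold is active.

### AFDF

Stage fusion starts from `X_i = L_i + G_i + bridge(fuse_{i−1})`, with
`fuse_0 = 0`. Multi-scale context is built by a *decomposed large
kernel*: a 5×5 depthwise convolution followed by a 7×7 depthwise
convolution (effective receptive field 11×11, asserted by an
impulse-response test). The concatenated scales (2C channels) form the
middle branch, gated by an MSCA module; the upper and lower branches are
the *channel sums* of each scale, single-channel spatial weight maps.
The fused map is `proj(U ⊙ Y_up + U ⊙ Y_down)` with a pointwise 2C→C
projection restoring the stage width. Two remarks:

* the sum-then-multiply form is retained as specified even though it is
  algebraically `U ⊙ (Y_up + Y_down)` — the identity is itself a test;
* the multi-scale convolutions carry **no normalisation layer**: a channel
  layer norm there zero-centres every pixel across channels and makes the
  channel-sum weight maps identically zero, collapsing the fusion output
  (we observed exactly this numerically). Bare depthwise convolutions
  match the fusion equations as written.

### Topology between stages

The fused output of stage *i* is the only tensor carried forward: one
shared downsample (layer norm + 2×2 stride-2 convolution with channel
doubling) produces the next stage's input, which both branches consume and
which also serves as `bridge(fuse_{i−1})` in the next stage's combination —
so the bridge adds no parameters. The alternatives (per-branch
downsampling with a separate learned bridge) are architecturally
plausible but count roughly 74 M parameters; the single-pathway topology
counts 68.4 M, matching the published budget of this architecture
(68.45 M / 9.24 G) to a fraction of a percent. We treat that printed
budget as an architectural constraint and fix all unstated widths by it:
`N = 4` FFEO blocks and purely depthwise multi-scale convolutions follow
from the same rule.

### Cost accounting

`count_parameters()` is an exact integer count over parameter shapes
(shape-only model builders avoid allocating the 68–88 M weights of the
reference models). `count_flops()` counts one multiply-accumulate as one
FLOP over convolution and dense layers — the convention under which the
two parent architectures' budgets are published; attention score/value
products, FFT/DCT transforms, normalisations and elementwise work are
excluded. The counter is validated by reproducing both baseline rows
(ConvNeXt-B 87.57 M / 15.35 G with an 8-class head; Swin-B 86.75 M /
≈15.16 G) before being applied to the fusion network (68.36 M / 9.09 G).

## Initialisation

Layers wrapped in norm + residual (the ConvNeXt and Swin block weights,
attention tables, excitation bottlenecks) use the parents' truncated
normal (sd 0.02). Bare convolution paths — stem, downsample, the AFDF
depthwise convolutions and projection — use fan-in-scaled He
initialisation: with sd 0.02 everywhere the AFDF product terms
(`U ⊙ channel-sums`) shrink the image-dependent signal to ~0.1% of the
feature magnitude and a desk-scale run cannot learn. Layer scale is
initialised at 1 (neutral): the 1e-6 convention of very deep parents
starves the convolutional branch of gradient at depth 2. These are
initialisation choices only; parameter shapes and counts are unchanged.

## Training protocol

`train_config()` defaults to the study protocol: Adam (decoupled weight
decay 0.01), initial learning rate 1e-4, batch size 16, 100 epochs, a
single cosine annealing cycle with floor 0 and no restarts (the final
epoch's rate is below lr₀/100). Best-validation-accuracy parameters are
retained; history is written as JSON lines; a non-finite loss aborts with
a diagnostic. Everything is seeded: parameter initialisation by the model
config seed, shuffling by the train config seed, and the image pipeline by
the generator seed — two runs with equal seeds produce identical losses.

Inputs are normalised per channel with mean 0.5 and sd 0.25 (fixed in the
model config); no augmentation is applied by default, matching a
resize-only pipeline.

## Metrics

Accuracy is `trace(confusion) / N`; precision, recall and F1 are computed
per class one-vs-rest and **macro-averaged** — the study reports single
values for 8-class tasks without naming the average, and macro is chosen
because BreaKHis class imbalance would otherwise mask minority-class
failure. A class never predicted has precision 0 by convention. One-vs-rest
ROC points are available via `roc_points()` (pROC when installed).
Embeddings (`extract_embeddings()`) are the pooled layer-normalised
pre-head features; the optional 2-D scatter uses PCA (no t-SNE
implementation is available here, and the export — not the projection —
is the reproducible artefact).

## Synthetic data: what it emulates, and what it does not

`generate_synthetic_dataset()` renders H&E-like patches: an eosin-pink
background modulated by a sinusoidal grating whose frequency encodes the
class (defaults: 2 classes × 16 images at 64 px, 4 vs 16 cycles/image,
random orientation and phase), hematoxylin-coloured elliptical nuclei
(3–8 per image, rejection-sampled so they never touch), and Gaussian
stain noise (sd 0.05). This makes the frequency-domain operators
discriminative *by construction* and gives the nucleus counter an exact
ground truth — `render_synthetic_bach_image()` does the same at slide
scale (1536×2048, 3×4 grid of 512-px cells) for the patch-extraction
rules.

What passing tests on this generator show: that the operators compute the
transforms they claim, that gradients flow end-to-end, that the pipeline
rules (tiling, the ≥20-nuclei filter at 512 px, grouped 0.6/0.2/0.2
splits) act as specified, and that the architecture has the capacity to
fit a small frequency-discriminable dataset. What they do not show:
performance on real stained tissue — real H&E has stain variability,
overlapping nuclei, scanner artefacts and class signal far subtler than a
single grating; the published accuracies on BreaKHis/BACH require the
original datasets and GPU-scale training and are outside this package's
test surface.

The nucleus counter itself is a standard stain-separation proxy
(optical-density transform, Ruifrok–Johnston H&E deconvolution, Otsu
threshold, connected components with area ≥ 40 px²). The upstream
literature delegates the exact procedure to a cited reference; this
parameterised stand-in reproduces its *filtering role* (patches with
fewer than 20 nuclei are excluded), and merged overlapping nuclei count
as one component — documented semantics, covered by tests.

## Numerical choices and degenerate inputs

* Window attention: the per-stage window is the largest divisor of the
  stage resolution not exceeding the configured size (7 at 224 input
  divides 56/28/14/7 exactly; reduced sizes shrink the window instead of
  padding); shifting is disabled when one window covers the map.
* Frequency partition with an odd bin count: the low-pass side takes the
  extra bin.
* Soft-shrink on complex values acts on real and imaginary parts
  independently, the simplest contract consistent with elementwise
  notation.
* `fuse_0 = 0` exactly: stage 1 has no bridge term and no bridge
  parameters.
* Checkpoints embed the full configuration; loading verifies every
  parameter shape and errors rather than reshaping.

## Problem sizes used by the test suite

Module tests run on maps up to 16×16 with finite-difference gradient
checks on every operator. Model-level tests use a reduced-width instance
(dims [16, 32, 64, 128], window 4) — the full reference widths are
exercised shape-only through the exact parameter/FLOP accounting. The
capacity check trains that reduced instance on the generator's standing
32-image task for 60 epochs at learning rate 1e-3 (the overfitting check
fixes its own rate; the protocol default remains 1e-4) and reaches 100%
training accuracy; on one CPU core this takes a few minutes.

## Known limitations

* No pretrained initialisation: the parents' ImageNet weights do not
  transfer onto this fused topology without a conversion step that is out
  of scope; `init = "random"` is the default and only built-in option.
* The FLOP counter reports the conv/linear MAC convention described
  above; conventions that include attention products or spectral MLPs
  will report higher figures for any windowed-attention model.
* Patient-level stratification for BreaKHis is not implemented
  (image-level splits, a `group` column provides the hook); BACH-style
  patches are always grouped by parent image.
* Training at reference scale (68 M parameters, 224 px) is far outside
  the intended desk scale of this implementation; the training loop is
  exercised and profiled on reduced widths.
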