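---
title: "Methods: microaneurysm segmentation with FC-DenseNets"
author: "mafcdn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microaneurysm segmentation with FC-DenseNets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, conventions and numerical choices behind
`mafcdn`, the way a methods section would: what is computed, under which
assumptions, and where the genuinely open design decisions were settled.

## The problem

Microaneurysms in fundus fluorescein angiography are bright, roughly round
spots of radius one to a few pixels, sitting on or near a much larger bright
vessel tree over a dark background. Two properties dominate the design of
any detector: the lesion/vessel intensity contrast is small, and the class
balance is extreme (typically well under 1 % of pixels are lesion). The
package treats detection as two-class semantic segmentation — every pixel is
background (including vessels) or microaneurysm.

## Preprocessing

Two pure, composable transforms, applied in the order stretch → filter.

**Histogram stretching.** Each frame's observed range `[I_min, I_max]` is
mapped linearly onto `[G_min, G_max]` (defaults 0 and 255), then rounded and
clipped. Properties relied on elsewhere: the map is monotone and hits both
endpoints exactly. The product `(G_max − G_min)(I − I_min)` is computed
before the division so that exact half-way values (e.g. 127.5) are
represented exactly and round deterministically. Rounding throughout the
package is *half away from zero* — deterministic and independent of the
platform's banker's rounding. A constant frame has no range to stretch;
the operation signals a typed degenerate-input condition, which batch
callers (`preprocess_dir()`, training, prediction) catch and turn into a
logged pass-through so one blank frame cannot abort a run.

**Gaussian filtering.** The discrete kernel is
`exp(−(x² + y²)/2σ²)` on the odd `l × l` integer offset grid, renormalized
to sum exactly 1 — any continuous prefactor cancels under this
renormalization, so none is applied. The kernel size does not follow from
the Gaussian itself; the default is `l = 2⌈3σ⌉ + 1` (≈3-sigma support), with
`σ = 1` px, both configurable (`gaussian_config()`). Convolution uses
mirror padding *without* repeating the edge pixel, which avoids the dark
halo that zero padding would paint around bright frame borders; a constant
frame is a fixed point, and the intensity range can never widen by more than
the rounding step. The implementation is checked exactly, pixel for pixel,
against a nested-loop reference in the test suite.

## The segmentation network

`build_fcdn()` constructs a fully convolutional DenseNet from an
`arch_config()`:

* initial 3×3 convolution (`first_conv_channels` maps);
* encoder: dense blocks (each layer = normalization → ReLU → 3×3
  convolution producing `growth_rate` maps → dropout) alternating with
  transition-down layers (normalization → ReLU → 1×1 convolution → dropout
  → 2×2 max pool);
* a bottleneck dense block;
* decoder: transition-up layers (3×3 transposed convolution, stride 2)
  alternating with dense blocks, each transition-up output concatenated
  with the matching-resolution encoder stack;
* final 1×1 convolution to 2 channels and per-pixel softmax.

Connectivity is deliberately asymmetric. Encoder dense blocks concatenate
their input with their output, so feature maps grow linearly
(`input + layers × growth`); decoder dense blocks forward **only** the
`layers × growth` new maps — otherwise the channel count would explode after
upsampling. This package applies the forward-only rule uniformly, including
the last decoder block (so the classifier sees `layers × growth` channels),
and lets a transition-up preserve the channel count of the maps it receives.
These two conventions fully determine every channel count and the trainable
parameter count; the test suite pins both against closed-form oracles
computed independently of the builder, for the named presets and custom
configurations.

The presets follow the reference FC-DenseNet family: 56 (blocks of 4,
growth 12), 67 (blocks of 5, growth 16) and 103 (encoder blocks 4, 5, 7, 10,
12, bottleneck 15, decoder 12, 10, 7, 5, 4, growth 16), all with a
48-channel first convolution and dropout 0.2. A `"tiny"` preset (first conv
16, growth 8, blocks of 2, no dropout) exists for CPU-scale smoke runs.

**Normalization statistics.** Training is per-frame stochastic descent
(batch size 1), so batch normalization computes per-sample spatial
statistics; the package uses the same per-sample statistics at inference
rather than running averages. This removes the train/inference statistics
mismatch entirely and makes prediction exactly deterministic — at the price
that a frame's prediction depends only on that frame, which is the natural
contract for single-frame screening.

**Initialization and optimizer.** Weights are He-uniform
(`±√(6/fan_in)`), seeded from the run configuration. The optimizer is
RMSprop (`lr 1e-3`, `ρ 0.9`, per-epoch exponential decay 0.995), the recipe
under which this architecture family was originally trained; the underlying
study names no optimizer, so this is a declared convention, fully
overridable in `run_config()`.

## Losses

With `p_t` the softmax probability of a pixel's true class,

* cross-entropy: mean of `−log p_t`;
* focal loss: mean of `−α_t (1 − p_t)^γ log p_t`.

`(1 − p_t)^γ` is monotone decreasing in `p_t`, so confidently classified
pixels — the ocean of easy background — contribute vanishing gradient, and
the scarce lesion pixels dominate. Defaults are the canonical
`α_MA = 0.25`, `α_background = 0.75`, `γ = 2`; the study left both
"adjustable", so they are plain config fields. `p_t` is clamped to
`[1e−7, 1]` inside both losses; the clamp is far below any metric
resolution and only exists to keep `log` finite. With `γ = 0` and unit
weights the focal loss reduces to cross-entropy exactly (a tested identity,
to 1e−10 relative tolerance), and the analytic gradient used by the training
loop is verified against finite differences.

## Evaluation metrics

From the 2×2 pixel confusion table `p[i][j]` (true class i, predicted j,
microaneurysm = positive class): PA, MPA, precision, recall, F1, MIoU. All
six agree with a brute-force loop implementation to 1e−12 on random tables.
Degenerate frames follow segmentation-suite conventions, chosen here because
the source material is silent: with no predicted positives, precision is 1
if there are also no true positives anywhere (an all-negative frame
predicted all-negative is correct) and 0 otherwise, symmetrically for
recall; F1 is 0 when precision + recall is 0; a class absent from both
prediction and truth contributes accuracy 1 and IoU 1 to the class means.
Aggregation is per image, then mean ± sample sd (n − 1) across the set —
the only reading consistent with reporting values as "mean ± small sd" over
a test set; a pooled-confusion mode (`pooled = TRUE`) sums tables first.

## The synthetic scene generator

`generate_sample()` emulates the *statistical* structure an FFA
microaneurysm detector faces, not angiographic optics: a dark background
plus a smooth bilinear illumination field; vessels as smoothed random-walk
strokes of constant intensity; lesions as radially decaying discs (peak at
centre, ~half peak at rim) placed preferentially within 10 px of a vessel
(90 % of placements), with bounded retries and a no-overlap rule; additive
Gaussian noise; and a global contrast compression toward mid-grey that
emulates washed-out raw frames. A pixel is lesion iff its centre lies
within the disc radius; vessels are background class, which is what makes
the task non-trivial — lesion and vessel intensities overlap.

Defaults (128×128, 3 vessels of width 2–5 px, 6 lesions of radius 1.5–3 px,
background 30, vessels 140, lesion peak 230, noise σ 4) keep the lesion
fraction below 1 % on average, reproducing the class imbalance. The `easy`
preset (peak 255 vs vessels 120, σ 2, no compression) is for smoke tests;
`hard` (compression 0.4, σ 8, peak 200 vs vessels 150) for ablation
demonstrations. Master seed → disjoint per-sample seeds → every pixel, so
`generate_dataset()` manifests allow bit-identical regeneration.

What passing tests on this generator shows: the pipeline can learn and
segment small bright low-contrast discs under heavy imbalance, end to end,
deterministically. What it does not show: performance on clinical FFA —
real lesion morphology, vessel texture, optic-disc glare and acquisition
artifacts are all absent, and no number produced on synthetic scenes is
comparable with clinically reported figures.

## Harness conventions

* **Determinism.** One master seed drives weight init, shuffling and
  dropout; training single-threaded; rerunning a persisted `run_config.json`
  on the same data reproduces `epochs.csv` byte for byte (tested).
* **Sizing policy.** Frame sides must be divisible by `2^depth`. Training
  centre-crops to the largest divisible size (a deterministic choice in
  preference to random crops, which would thread extra RNG draws through
  the determinism contract); inference reflect-pads up and crops the
  prediction back, so output size always equals input size.
* **Checkpoints** are self-describing (weights + full run config including
  preprocessing), so `predict` and `evaluate` never need the original
  config file. Model selection is best validation MIoU; early stopping
  patience 20 epochs.
* **Decoding** is per-pixel argmax; no threshold is tuned.
* **Ablation.** `run_ablation()` trains the three classic arms —
  preprocessing + cross-entropy, focal only, full pipeline — under one seed
  and split, and emits the six-metric comparison table. Failed arms are
  marked, not fatal.

## Problem sizes

Desk-scale conditions used by the tests and the acceptance script, chosen
once as realistic for the task at this scale: smoke training = 200 easy
64×64 frames (3 lesions, 2 vessels each — the 128×128 default density
scaled by area), tiny preset, 3 epochs, seeds 1–3, thresholds F1 ≥ 0.6 /
MIoU ≥ 0.65 on 24 held-out frames; ablation grid = 30/6/6 frames, 2 epochs.
Full 768×868 frames are supported by the same code paths but are not
exercised in routine testing.

## Limitations

The engine is CPU-only and per-frame; it is built for reproducibility and
study at desk scale, not throughput. Vessels are not a separate class, so
nothing prevents a model from calling a bright vessel crossing a lesion;
only pixel-level metrics are reported (no lesion-level counting). The
synthetic generator's parameters are order-of-magnitude choices exposed in
configuration, not fitted to clinical measurements.
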