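---
title: "Attention Squeeze U-Net: model, training loss and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention Squeeze U-Net: model, training loss and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asunet)
```

## The problem

Dermoscopic lesion-area segmentation produces a binary mask separating a skin
lesion from the surrounding healthy skin. It is the first step of any
quantitative lesion-tracking pipeline (the "E" of the ABCDE rule), and for
privacy-preserving, on-device use the network must be small: a classic U-Net
carries over 30 million trainable parameters, far more than comfortable on an
embedded board. The Attention Squeeze U-Net combines two parameter-saving
ideas — SqueezeNet-style *fire* modules and additive *attention gates* on the
skip connections — into an encoder–decoder that carries about 2.5 million
parameters, roughly one twelfth of U-Net, while keeping U-Net's symmetric
skip-connection layout.

## Architecture

Four architectures are implemented behind one interface
(`network_spec()` / `build_network()`): `unet`, `attention_unet`,
`squeeze_unet` and `attention_squeeze_unet`.

**Fire block.** A 1x1 "squeeze" convolution reduces the input to $C_S$
channels; two parallel "expand" convolutions (3x3 and 1x1) each produce
$C_O/2$ channels and are concatenated, so $C_O$ must be even. All
convolutions use same-padding and ReLU. The transposed variant
(`transposed_fire_block()`) replaces the squeeze with a 1x1 transposed
convolution (stride 2 doubles the spatial size) and expands with parallel
1x1 and 2x2 convolutions.

**Attention gate.** The gate receives a coarse gating signal $g$ (upsampled to
the skip's spatial size) and the skip features $x$. Both are projected by 1x1
convolutions to a common intermediate width, summed, passed through ReLU and a
1x1 convolution to a single channel, and squashed by a sigmoid into a
per-pixel map in $(0,1)$ that multiplies $x$. The intermediate width is half
the gating channels; this choice (rather than half the skip channels) keeps
the four gates' overhead at 107,636 parameters, matching the printed "about
100k more than Squeeze U-Net" figure.

**Upsampling block.** A 3x3 stride-2 transposed convolution turns $g$ into
$\hat g$ at the skip's resolution; the gated skip (or the raw skip in the
non-attention variant) is concatenated with $\hat g$ and passed through a fire
block.

**Channel schedule.** The per-stage channel counts are not printed anywhere,
only drawn; the published parameter totals are the arbiter of the
reconstruction. The schedule below reproduces them exactly
(`squeeze_unet` = 2,457,002 ≈ 2.5M; `attention_squeeze_unet` adds 107,636
≈ 100k; `unet` = 31,031,810 > 30M):

| stage | operator | output channels | resolution |
|---|---|---|---|
| stem | conv 3x3, stride 2 | 64 | 1/2 |
| enc 1 | pool; fire(16) x2 | 128 | 1/4 |
| enc 2 | pool; fire(32) x2 | 256 | 1/8 |
| enc 3 | pool; fire(48) x2 | 384 | 1/16 |
| enc 4 | pool; fire(56), fire(64) | 448, 512 | 1/32 |
| up 1 | deconv to 192 (stride 1) + gate + fire(64) | 384 | 1/32 |
| up 2 | deconv to 128 + gate + fire(32) | 256 | 1/16 |
| up 3 | deconv to 64 + gate + fire(16) | 128 | 1/8 |
| up 4 | deconv to 32 + gate + fire(16) | 64 | 1/4 |
| head | nn x2 + conv 3x3; nn x2 + conv 3x3; conv 1x1 | 32, 16, 2 | 1/2, 1, 1 |

The expansive path thus contains four fire-based upsampling blocks, two plain
convolutional layers and two nearest-neighbour upsampling stages; whether the
nearest-neighbour stages carry trainable convolutions is not stated in the
figure, and here each resize is followed by one 3x3 convolution. The final
1x1 convolution feeds a per-pixel softmax over two channels — background is
treated as its own class, so channel sums are 1 everywhere. Inputs must be
divisible by 32 (16 for the U-Net family). Weights are Glorot-uniform,
seeded from `network_spec(seed = )`; batch normalization is not used.

The engine behind these models (convolutions via im2col + BLAS, transposed
convolutions as the exact adjoint of a strided convolution, 2x2 max-pooling,
reverse-mode differentiation, Adam) is part of the package and is verified
against central-difference numeric gradients in the test suite.

## Training loss

Training minimizes the Focal Tversky loss on the foreground channel:
$$\mathrm{TI} = \frac{\mathrm{TP}}{\mathrm{TP} + \alpha\,\mathrm{FN} + \beta\,\mathrm{FP}},
\qquad \mathrm{FTL} = (1 - \mathrm{TI})^{\gamma},$$
with soft counts $\mathrm{TP} = \sum p\,g$, $\mathrm{FN} = \sum (1-p)\,g$,
$\mathrm{FP} = \sum p\,(1-g)$ and an $\epsilon = 10^{-6}$ smoothing of the
ratio against empty masks. Defaults $\alpha = 0.7$, $\beta = 0.3$,
$\gamma = 4/3$ follow the Focal Tversky literature: $\alpha > \beta$
penalizes missed lesion pixels more, and $\gamma > 1$ concentrates gradient
on poorly segmented images. $\alpha+\beta=1$ is deliberately not enforced —
the Jaccard corner of the Tversky family needs $\alpha=\beta=1$. Batch losses
are the mean of per-image FTL values rather than pooled pixel counts, so
small-lesion images are not swamped by large ones. All four values are
configurable through `tversky_params()`.

## Preprocessing and augmentation

Images are resized to 384x512 (bilinear) and normalized to $[0,1]$; masks are
resized with nearest-neighbour interpolation, which preserves binarity, and
binarized at 127/255 when read from 8-bit PNGs. Augmentation materializes the
three flips (vertical, horizontal, both) of every training pair ahead of
training — 2,000 pairs become exactly 8,000 — rather than flipping
stochastically per epoch, matching the fixed published count. Flips are exact
row/column reversals, so they conserve foreground area and confusion counts.

## Training protocol

`train_config()` defaults: Adam with learning rate $10^{-3}$, batch size 8,
100 epochs. The optimizer, learning rate and batch size are not stated in the
source protocol; these are this package's own defaults and live in the
config. Model selection deliberately differs from the reference protocol,
which kept the model scoring best on the *test* set: selecting on test data
is leakage, so this implementation selects the best epoch by validation Dice
(configurable) and keeps that checkpoint. A fixed seed covers weight
initialization, shuffling and data generation, making runs bit-reproducible
on one platform.

## Evaluation

`evaluate_dataset()` scores predictions at ground-truth resolution with
pixel accuracy, Dice, Jaccard and the Threshold Jaccard (zero below 0.65,
strict `<`, as proposed for ISIC 2018). Aggregates are macro averages —
per-image metrics averaged within the dataset or within a lesion class —
which is how challenge leaderboards aggregate; whether the reference tables
were macro or micro averaged is not stated. Images with JSI < 0.65 form the
failure list ("unusable" segmentations). `comparison_image()` renders the
TP/FP/FN/TN classes as green/red/blue/black overlays whose color histogram
is exactly the confusion counts.

## Synthetic data

Real dermoscopy archives cannot ship with a package, so `synth_config()` /
`generate_sample()` emulate their testable structure: a textured skin
background; an elliptical lesion whose boundary radius is modulated by
low-order harmonics (amplitude = "irregularity"); darker lesion shading with
a soft edge; and the four classic artifact types — dark hair polylines,
bright bubble rings, pen-mark arcs outside the lesion, and saturated specular
highlights. The mask is exactly the rasterized lesion support: there is no
label noise. The lesion radius is solved from the polar area integral so the
foreground fraction lands inside the configured range. Class presets give
the seven lesion classes distinguishable morphology statistics (nevi
near-symmetric, melanomas highly irregular, dermatofibromas small and
sharply demarcated, actinic keratoses low-contrast), and every sample is a
pure function of `(seed, index)`, recorded in a YAML manifest.

What passing tests on this generator do *not* show: robustness to real
acquisition variability — color constancy, ruler markers and band-aids,
ambiguous expert boundaries, multi-focal lesions. Scores on synthetic
fixtures say the pipeline is wired correctly, not that it reaches the
published Dice on ISIC/PH2; that requires the real archives and full-scale
training.

## Numerical choices and problem sizes

* Degenerate empty-vs-empty masks score Dice/Jaccard 1 (configurable).
* Softmax is stabilized by per-pixel max subtraction; predictions binarize by
  argmax, which for two classes equals thresholding the foreground
  probability at 0.5.
* Transposed convolutions specify their output size explicitly (exactly
  stride x input), avoiding off-by-one dialect differences; padding follows
  the "same" rule with the extra pixel on the bottom/right.
* Divergence (non-finite loss) aborts training, reporting the last finite
  epoch.
* Test fixtures default to 96x128 — the 3:4 aspect of 384x512 at quarter
  scale, divisible by 32 — so the full training loop, the 300-step overfit
  check (4 images, batch 4) and the 2,000-sample augmentation check run on a
  single CPU; the full 384x512 resolution is exercised for construction,
  parameter counting and single forward passes.

## Limitations

Single-image (batch-size-1) statistics only — no batch normalization; no GPU
path; no pretrained weights; no color-constancy or hair-removal
preprocessing; multi-class (>2) soft losses and boundary-distance metrics
(e.g. Hausdorff) are out of scope.
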