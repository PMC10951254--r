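---
title: "Coronary vessel segmentation with angioseg: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coronary vessel segmentation with angioseg: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`angioseg` segments coronary vasculature in single-frame X-ray angiograms.
This vignette is the package's account of its science: the enhancement
front end, the network and loss, the training protocol, the synthetic data
model used for testing, and the numerical and design choices behind them.

## The problem

In contrast angiography the arteries are filled with radio-opaque medium and
appear *darker* than the surrounding tissue. Frames are low-contrast and
noisy; the catheter is filled with the same medium and looks like a vessel;
ribs create wide, low-contrast bands. Vessel pixels are typically only a few
percent of the frame, so a segmenter faces both low signal and extreme class
imbalance.

## Dual-phase contrast enhancement

`preprocess_pipeline()` applies unsharp masking and then two CLAHE filters
to the sharpened image, stacking the three results as one 3-channel input:

* **Unsharp masking** (`unsharp_mask()`): `clip(x + amount · (x − G_σ(x)))`,
  with Gaussian blur `G_σ` computed with replicate-padded borders so constant
  images are exact fixed points. Defaults `σ = 2` px, `amount = 1.5`.
* **CLAHE** (`clahe()`): per-tile 256-bin histograms clipped at `clip_limit`
  times the uniform bin height, excess redistributed uniformly; each tile's
  CDF gives a monotone intensity mapping and pixels are remapped by bilinear
  interpolation between the four surrounding tile mappings. Non-divisible
  image sides are mirror-padded and cropped back. With a single tile and an
  unbounded clip limit the operation reduces exactly to global histogram
  equalization — a limit used as an oracle in the test suite. Defaults:
  channel 2 uses clip 2.0 on an 8×8 grid (conservative), channel 3 clip 4.0
  on a 16×16 grid (aggressive, more local).

The source never states the "tuned parameters" of either filter, so the
defaults are conventional values for 512 px 8-bit radiographs and are fully
exposed in `preprocess_params()`; the contract is the pipeline structure.
Both CLAHE channels operate on the USM output (serial USM, parallel CLAHE),
the reading most consistent with a sharpen-then-equalize cascade. All
internal arithmetic is 8-bit (0–255, the conventional 256 histogram bins);
normalized inputs are rescaled in and back out.

## SE-RegUNet

`build_se_regunet()` assembles an encoder–decoder network:

* **Encoder**: a RegNet-style backbone generated from the quantized linear
  design rule (per-block widths `u_j = w0 + wa·j` snapped to the geometric
  grid `w0·wm^s`, grouped into stages, widths adjusted for group-convolution
  compatibility). Two full-scale presets are built in — the Y-family 16GF
  design (widths 224/448/1232/3024, residual bottlenecks with SE and ReLU)
  and the Z-family 4GF design (widths 48/104/240/528, inverted ×4
  bottlenecks with SE, SiLU, identity-only shortcuts) — plus a `"tiny"`
  desk-scale preset (stem 8, stages 16/32/64) with the same topology.
* **Decoder**: per stage, ×2 bilinear upsampling, concatenation with the
  skip feature, two conv3×3–BatchNorm–ReLU layers, and a
  squeeze-and-excitation gate (global average pool → bottleneck of ratio
  `r = 16` → sigmoid gates multiplying each channel). The stride-2 stem
  features serve as the shallowest skip; a final ×2 upsample restores full
  resolution before a 1×1 two-class head. Upsampling is bilinear rather
  than transposed convolution: fewer parameters, no checkerboarding.
* **Head**: softmax over the two channels, so each pixel's class
  probabilities sum to one.

Decoder widths are not stated by the source; the package derives them from
the deepest encoder width `C5` as `(C5/2, C5/4, C5/8, C5/16)` with a
post-upsample refinement width of `C5/32`. This single rule reproduces the
published complexity of *both* variants (about 29.8M parameters and
27.2 GFLOPs at 512 px for the 4GF model; about 184M parameters for the 16GF
model) — a flat width set matching one variant cannot match the other. The
profiler (`profile_complexity()`) counts parameters exactly and
convolution/linear multiply-accumulates analytically, with one MAC counted
as one FLOP (the convention under which the backbones carry their
"gigaflop" names).

The LCA/RCA classifier (`build_classifier()`) reuses the encoder with global
average pooling and a linear head emitting the probability of a left
coronary tree.

## Loss

Training minimizes a class-weighted focal loss,
`α (1 − p_t)^γ · w_y · (−log p_t)` averaged over pixels, with `α = 0.8`,
`γ = 2`, background weight 1 and vessel weight 20. The printed form of this
loss in the source literature inserts the scalar weighted cross-entropy
where the standard focal loss has the true-class probability; read literally
it would take the logarithm of a loss value. The package implements the
standard per-pixel reading (which recovers the printed formula when "WCE" is
read as the cross-entropy's inner probability) and exposes the literal
scalar-modulated variant behind `focal_loss(..., literal = TRUE)` for
comparison. True-class probabilities are clamped at `1e-7` so the loss is
never infinite. The gradient with respect to the logits is computed in
closed form and verified against finite differences in the tests.

## Training protocol

`make_splits()` holds out 20% of images (an explicit count can override the
fraction, for protocols that state exact sizes) and partitions the rest into
five folds; splitting is by patient when patient ids exist, preventing
leakage across frames of one acquisition. `cross_validate()` trains one
fresh model per fold and reports mean ± SD of Dice, accuracy, sensitivity,
specificity and precision.

The optimizer (`ranger21_style`) is AdamW plus the headline components of
the Ranger21 composite: linear warm-up (10% of steps), cosine decay, and
gradient centralization on convolution kernels; plain `adamw` is available.
Full-scale defaults mirror the study protocol: 200 epochs, batch 8, 512 px,
learning rate 0.001, five folds; there is no early stopping — the only model
selection is the best-validation-Dice checkpoint.

**Desk-scale preset.** The scaled-down experiments in the test suite train
the `"tiny"` backbone with decoder widths divided by 4 on 200 synthetic
256 px images for 10 epochs at batch 4, with the same focal loss, and use a
learning rate of 0.01: at a few hundred optimizer steps the full-scale rate
of 0.001 moves AdamW's near-unit-magnitude updates far too little to
converge, while 0.01 reaches a held-out Dice above 0.8 within the 10-epoch
budget. The side classifier trains on the same images downsampled to 64 px
for 20 epochs — side information is a global, low-frequency property, so the
lower resolution loses nothing. These problem sizes were chosen so the whole
experiment runs in minutes on one CPU.

## Synthetic angiograms

`generate_tree()` draws a branching tree of curvature-limited random
centerlines rooted at the left (LCA) or right (RCA) image border, with
root widths of 4–9 px tapering by 0.6–0.9 per generation, rasterized as
disks along the path. Vessels are drawn *darker* than background by a
per-branch contrast of 20–60 intensity units with a slow along-branch
modulation (uneven filling). The background is mid-gray with a low-frequency
sinusoidal illumination gradient (amplitude 30) and Gaussian noise (σ = 8).
With probability 0.3 each, a high-contrast near-straight catheter touches
the root (drawn in the image, *excluded* from the mask — mirroring clinical
labeling and enabling tests of the catheter-confusion failure mode) and
wide low-contrast diagonal rib bands are added. Generation is deterministic
given `(spec, seed)`; under the default spec the vessel fraction stays
within the strong-imbalance regime (about 0.5–15% of pixels) that motivates
the vessel weight of 20.

What the generator does *not* emulate: projective foreshortening, vessel
overlap from multiple viewing angles, stenotic narrowing, motion blur,
table panning, or cine sequences. Passing the scaled-down experiments
therefore shows that the architecture, loss, optimizer and pipeline learn
and route correctly on angiogram-like statistics — not that the trained
weights transfer to clinical images; full-scale training on real labeled
angiograms remains necessary for that.

## Numerical choices and degenerate inputs

* Tensors are `(H, W, C, N)` double arrays; convolutions run as im2col +
  GEMM through RcppArmadillo and are validated against a naive convolution
  oracle and finite differences.
* Batch norm uses ε = 1e-5, momentum 0.1, biased batch variance; evaluation
  mode uses running statistics, so eval-mode inference is deterministic.
* Dice of two empty masks is defined as 1 (perfect agreement on absence);
  confusion ratios with zero denominators are flagged `NA` and excluded
  from aggregation.
* Binarization is argmax over the two softmax channels (equivalently a 0.5
  threshold on the vessel probability).
* AUC is the Mann–Whitney statistic with ties counted one half; degenerate
  single-class label vectors are an error.
* Masks on disk are 0/255 PNG; in memory 0/1. Coordinates are row-major,
  origin top-left, 0-based in documentation of pixel positions.
* Images smaller than the Gaussian kernel are handled by replicate padding
  before filtering; CLAHE mirror-pads non-divisible tile grids.

## Known limitations

* The engine is CPU-only and double-precision; full-scale (512 px, 30M+
  parameter) *training* is out of desk reach — the full-scale models are
  built and profiled, and their learning dynamics are exercised at reduced
  width and resolution.
* One architecture serves both coronary sides; the bundle can hold two
  weight sets (per-side routing) or alias one set for both, and the
  classifier's AUC on synthetic trees (> 0.95) overstates how easy routing
  is on clinical images.
* The catheter remains the known failure mode: it is excluded from ground
  truth but shares the vessels' intensity profile, and the synthetic tests
  probe, not solve, that confusion.
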