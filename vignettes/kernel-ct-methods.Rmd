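---
title: "Segmenting and phenotyping maize kernel endosperm from micro-CT"
author: "kernelCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and phenotyping maize kernel endosperm from micro-CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kernelCT)
```

## The problem

A maize kernel's endosperm is split between a hard, glassy *vitreous* region
near the periphery and a soft, floury *starchy* region at the centre. Their
ratio drives kernel texture, milling behaviour and breeding value, but the
classical measurement — dissecting kernels and photographing cross-sections —
is destructive and slow. X-ray micro-computed tomography images the intact
kernel as a stack of 8-bit grayscale slices, at the price of two imaging
difficulties: the two endosperm classes differ by only a few dozen intensity
units, and the transition between them is gradual, so plain thresholding
over- or under-segments.

`kernelCT` implements the full analysis chain: extracting single kernels from
batch scans, segmenting vitreous vs. starchy endosperm with an
attention-augmented U-Net trained under a composite focal-Tversky plus
boundary-smoothing objective, and converting label volumes into texture
phenotypes. A deterministic phantom generator stands in for scanner data, so
every stage is testable end to end.

## Data model

A `CTVolume` holds the slice stack as a numeric array ordered `(z, y, x)`
with a physical voxel edge length in micrometres; a `LabelVolume` holds the
aligned class map over `{0, 1, 2}` (background, starchy, vitreous). Two
remarks on conventions that are easy to trip over:

* **Voxel size.** The default voxel edge is 27 µm, the value used for
  volumetry in the source protocol, but it is an explicit, overridable
  argument everywhere: scanner resolution settings vary (a nominal
  acquisition resolution of ~13.6 µm is equally plausible for this class of
  scanner), and all volumes scale with its cube.
* **NIfTI orientation.** Label volumes read from NIfTI are taken in *stored*
  order with the slowest axis as z; orientation codes are deliberately
  ignored. Volumes written by the package round-trip exactly; files produced
  by other tools are not reoriented.

## Preprocessing

Raw batch scans hold several kernels per field of view. `splitBatchScan()`
finds them with a classical chain: per-slice Canny edges (Gaussian blur,
Sobel gradients, non-maximum suppression, hysteresis), morphological closing
and hole filling, then 26-connected 3D component labelling. The largest
`expectedKernels` components are kept and cropped with a 5 % margin. Defaults
that were open choices:

* Canny's high threshold is the Otsu threshold of the slice intensities and
  the low threshold half of that — parameter-free for bright-kernel scenes,
  and overridable.
* The minimum component size is 0.1 % of the volume, which suppresses speckle
  without ever approaching kernel size at any realistic scale.
* Components tie-break by smaller centroid x, and crops are returned left to
  right, so outputs are deterministic.
* Bounding boxes are 0-based, half-open index ranges throughout.

`clampPixels()` implements plain intensity truncation (with 8-bit default
bounds it is the identity — it exists for non-default bounds and defensive
use), `remapLabels()` maps annotation exports (e.g. 255/128) onto `{1, 2}`
while refusing any unmapped value, and `enhanceContrast()` defaults to a
p1–p99 percentile stretch because it is monotone and closed-form testable;
CLAHE is available by name. `standardizeForModel()` resizes each crop slice
aspect-preserving to the model's input side (256 by default), zero-pads, and
rescales to `[0, 1]`.

## The segmentation network

The segmenter is a five-level U-Net. Each encoder level applies two
3×3 convolution–batch-norm–ReLU blocks, a CBAM attention block, and 2×2 max
pooling (four poolings in total); the decoder mirrors it with learned 2×2
transposed-convolution upsampling (bilinear by flag), skip concatenation, the
conv pair, and a squeeze-and-excitation (SE) block; a 1×1 convolution maps to
the three class logits. CBAM rescales features per channel (shared two-layer
MLP over global average- and max-pooled descriptors, sigmoid) and then per
position (7×7 convolution over the channel-mean and channel-max maps,
sigmoid); SE is the channel half alone with global average pooling. Ablation
switches (`useCBAM`, `useSE`) reduce the model to a plain U-Net baseline.

Design points that were genuinely open:

* Channel counts default to the doubling rule 64…1024; `capFilters = TRUE`
  caps them at 512 for a lighter model. Attention reduction ratios default to
  16, the convention of the attention literature.
* The skip connection is taken *after* the encoder CBAM, so the decoder sees
  attention-weighted features; CBAM is not applied at the bottleneck (no pool
  follows it) unless `cbamAtBottleneck = TRUE`.
* Convolutions use same-padding so skips concatenate without cropping; inputs
  must be divisible by `2^(levels-1)`, enforced with a clear error.

There is no deep-learning framework dependency: forward and backward passes
are written against BLAS matrix products, with the convolution inner loops
(im2col gathering and the scatter-add of the data gradient) in compiled code.
Every analytic gradient is verified against central finite differences in the
test suite; parameter initialisation (He) is fully determined by a seed.

## The training objective

Per foreground class (one-vs-rest on softmax probabilities, background
excluded, classes equally weighted) the loss combines:

* **Focal Tversky**: `alpha * (1 - T)^gamma` with
  `T = |X∩Y| / (beta |X| + (1-beta) |Y|)` (stabilised by `epsilon`),
  `beta = 0.75` and `gamma = 2` — the asymmetry weights false negatives
  harder and the exponent focuses training on poorly-segmented classes. The
  denominator is implemented exactly in this two-mask form; a `variant`
  switch provides the equivalent `TP + beta FN + (1-beta) FP` form (the two
  coincide on hard masks with the beta roles swapped). At `beta = 0.5` the
  index reduces to Dice.
* **Boundary smoothing**: `lambda * sum((|grad pred| - |grad true|)^2)` over
  pixels, with a forward-difference gradient (edge-replicated, so border
  differences are zero; Sobel by flag). It pushes the prediction to place
  sharp transitions exactly where the reference has them — the mechanism
  aimed at the blurred vitreous/starchy interface.

`alpha` defaults to 1 (no reference value exists; it is a pure scale).
`lambda` also has no reference value, and its choice matters more than it
looks: the boundary term is an *unnormalised sum over pixels* whose raw
magnitude scales with the class-boundary perimeter — hundreds on 128–256
pixel slices — while the focal Tversky term lives in `[0, 1]`. A weight of
0.1 makes the objective ~97 % boundary matching, and even 0.005 measurably
slows the overlap term's convergence on the phantom task; the package
default `lambda = 0.001` (roughly one over the typical perimeter) keeps the
two terms on a comparable scale so the boundary penalty refines rather than
dominates. `lambda = 0` recovers the pure focal Tversky objective exactly.

Training follows the reference protocol: RMSprop (smoothing 0.99, no
momentum), batch size 1, 50 epochs, initial learning rate 1e-4 with a floor
of 1e-5. The schedule connecting the two rates is unspecified in the
protocol; the default halves the rate after 5 epochs without validation
improvement (cosine decay by flag). Augmentation (flips, 90° rotations) is
available but off by default. The 8:1 train:validation split is per sample
id; when ids index kernels rather than slices this prevents slice leakage
between splits. The best-validation checkpoint (highest mean foreground
Dice) is kept.

## Phenotype extraction

From a single-kernel volume and its label volume, `computePhenotypes()`
produces the five texture phenotypes plus bounding-box dimensions:

* **V** — seed volume from the whole-seed mask: Otsu foreground threshold,
  largest 3D component, per-slice hole filling. V includes the pericarp and
  germ, so `VV/V + SV/V < 1` in general.
* **VV, SV** — vitreous and starchy volumes by voxel counting:
  `count × edge³`. Voxel counting is exact with respect to the mask; no
  surface mesh is involved in measurement.
* **VV/V, SV/V** — the texture ratios.
* **length ≥ width ≥ thickness** — the sorted edge lengths of the tight
  axis-aligned bounding box of the seed mask, in micrometres.

`separateClassMasks()` accepts either label volumes (split by code) or
grayscale mask renderings, which are split by an Otsu threshold on the
nonzero-intensity histogram (the brighter class is vitreous). The Otsu
implementation is an exhaustive 256-cut maximisation of between-class
variance with ties broken toward the lower cut — note that for a cleanly
bimodal histogram every cut inside the empty gap is optimal, so the reported
threshold is the gap's lower edge; the induced partition is identical.
`aggregateByGroup()` computes the per-subgroup summary statistics (n, mean,
median, sd, quartiles, range) that underlie subgroup box plots.

## The phantom generator

`generateKernelPhantom()` renders nested ellipsoids: a starchy core
(`rho <= coreFraction`), a vitreous shell (`coreFraction < rho <=
shellFraction`), a pericarp rim out to the seed surface, on a dim background.
The image applies per-region mean intensities, per-slice Gaussian blur, and
additive Gaussian noise, clamped to `[0, 255]`; the *labels stay crisp*
(pre-blur), which reproduces exactly the ambiguity the boundary-smoothing
term targets: a blurred image boundary with a sharp reference boundary.
Default intensities (background 20, starchy 150, vitreous 180, pericarp 220)
give a deliberately small 30-unit endosperm contrast against 8-bit noise of
sd 6 and 1-voxel blur — low class contrast, bright seed outline — chosen once
as a realistic miniature of kernel CT contrast. The generator's truth record
(exact per-class voxel counts, centroid, bounding box) is the oracle for
split, volumetry and phenotype tests.

`makeTrainingSet()` samples single-slice phantoms with ellipse semi-axes
26–42 % of the image side, core fraction 0.45–0.65, shell fraction 0.78–0.92,
noise sd 4–8 and blur 0.7–1.3 — wide enough that a model must learn shape and
intensity jointly, narrow enough to stay kernel-like. What the phantoms do
*not* emulate: beam hardening and ring artifacts, the germ and internal
cavities, non-ellipsoidal kernel shapes, and intensity inhomogeneity across
the field of view. A model that segments phantoms well has demonstrated the
pipeline's mechanics, not performance on real scanner data.

## Numerical choices and degenerate inputs

* Tversky ratio stabiliser `epsilon = 1e-6`; empty-vs-empty Dice and IoU are
  defined as 1 (both sets empty is perfect agreement).
* The boundary gradient at zero magnitude has a zero subgradient in the
  analytic backward pass.
* Max pooling and argmax predictions break ties deterministically toward the
  first candidate; connected components order by size with centroid
  tie-breaks; all stochastic stages (init, shuffling, noise, augmentation)
  are seeded and restore the caller's RNG state.
* Constant images: contrast stretch returns them unchanged; Otsu refuses a
  single-mode histogram with an explicit error rather than emitting an
  arbitrary threshold.
* Batch-norm statistics are per-image (batch size 1); inference uses running
  statistics and is fully deterministic.

## Problem sizes in the checks

The test suite and the acceptance script exercise the implementation at
deliberately small scale, chosen so every quantity has an independent oracle:
exhaustive 3×3 mask enumeration (all 2^9 × 2^9 pairs) for the loss/metric
layer; 16³ random masks against triple-loop voxel counting; a digitised
40×30×20-voxel ellipsoid against the analytic volume; three-kernel synthetic
scenes for batch splitting; and a segmentation-recovery surrogate — 64
training slices of 128×128, a reduced network (3 levels, base 16 filters),
10 epochs — evaluated on 16 held-out phantoms, where the trained model reaches
mean foreground Dice well above 0.8. Full-size behaviour (five levels, base
64, 256×256 input) is checked structurally: shape contracts, attention-weight
ranges, and build determinism.

## Known limitations

* Per-slice 2D segmentation: no 3D convolutions; volumetric consistency
  comes only from the slice stack.
* The hand-written training loop is single-image RMSprop; it is adequate for
  the package's scale but not tuned for large-corpus throughput.
* NIfTI orientation metadata is ignored by design; mixing sources with
  different storage orders is the caller's responsibility.
* Phantom realism bounds what passing tests prove about scanner data (see
  above); no claim is made of reproducing results on any private CT corpus.
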