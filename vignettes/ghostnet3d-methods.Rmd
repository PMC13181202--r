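---
title: "Methods: 3D ghost residual networks for nodule malignancy classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D ghost residual networks for nodule malignancy classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Malignancy assessment of a pulmonary nodule from chest CT is a 3D pattern
recognition problem: the discriminative cues — diameter, contrast against the
lung parenchyma, and marginal spiculation — are volumetric, so the classifier
in this package consumes a `32^3` single-channel patch centred on the nodule
and emits benign/malignant confidences through a 3D residual network.

Two architectural ideas shape the network family (`network_config()`,
`build_network()`):

**Ghost convolutions.** A standard 3D convolution with `c_out` filters spends
`k^3 c_in c_out` weights. A ghost module computes only
`m = ceiling(c_out / s)` "base" maps with the standard kernel, then
synthesizes the remaining `c_out - m` maps with cheap `3^3` *depthwise*
convolutions of the base maps, and concatenates both sets. For ratio `s = 2`
and `k = 3` the per-layer weight cost tends to half the plain cost as
channels grow. Each branch carries its own normalization and activation, the
structure of the original ghost module; at `s = 1` the module degenerates
exactly (bitwise, tested) to the plain convolution.

**Hybrid normalization–activation.** Every convolution is followed by a
norm–affine–activation module. Because training runs at batch size 2, batch
statistics are unreliable where activations still resemble the raw image, so
the trunk (stem) normalizes with *layer norm* (per sample over all channels
and voxels) while the residual blocks use *batch norm* (per channel, running
statistics with momentum 0.1 in eval mode). Both carry per-channel affine
gain and bias — the learnable `w`, `b` of the module — and are followed by
ELU by default. Instance norm and weight norm (a reparameterization of the
preceding convolution; its activation-statistics branch is a no-op) plus
ReLU/LeakyReLU/GELU fill out the ablation grid, which the test suite builds
and runs exhaustively.

The flagship genotype is a 50-layer bottleneck network: stem `3^3`
convolution (64 channels, stride 1) + `3^3`/stride-2 max pool, four stages of
(3, 4, 6, 3) bottleneck blocks with base widths (64, 128, 256, 512) and
expansion 4, stride-2 spatial reduction in the `3^3` convolution of the first
block of stages 2–4, ghost modules (s = 2) in every block convolution, `3^3`
*ghost* projection shortcuts, global average pooling, and a 2-way head.
Convolutions carry no bias (an affine norm follows every one); the classifier
head is zero-initialized so an untrained network is exactly symmetric, and
all other weights are He-normal, deterministic in the build seed.

## Complexity accounting and its calibration

`count_parameters()` is a closed-form walk over the layer shapes (verified in
the tests against a brute-force walk over every allocated tensor). The
baseline (plain convolutions, `1^3` shortcuts, BN+ReLU) counts 46,138,946
trainable scalars — 46.14 M — and the full ghost network 59,505,282 — 59.51 M.
The increase is driven entirely by the `3^3` ghost downsample shortcuts; the
hybrid norm modules add no parameters relative to plain norm+activation
because their `w`, `b` *are* the norm's affine pair.

`count_macs()` reports multiply-accumulate-equivalent operations for one
forward pass. Two conventions are provided. `"conv_linear"` counts
convolution and linear MACs only. The default `"op"` convention mirrors the
widely used profiler convention: conv/linear MACs plus 2 ops per element for
a normalization, 1 per element for an activation, 1 per input element for a
pooling window pass, and 1 per element for a residual addition. Under `"op"`
the baseline costs 4.44 Gmac and the full network 4.82 Gmac at `1×32^3`. The
choice among stride placements (reduction in the `3^3` bottleneck conv;
stride-1 stem plus pool) and the `"op"` convention were calibrated jointly so
that the whole four-way family — plain/ghost × `1^3`/`3^3` shortcuts — lands
on a consistent budget; the package treats that calibrated pair as part of
the architecture definition.

## Training

`train_control()` encodes the optimization recipe: AdamW (decoupled weight
decay 0.01 on conv/linear weights only), batch size 2, initial learning rate
2e-4, 200 epochs with the rate constant for the first 130 and then decayed —
the default decay is linear-to-zero and the schedule is pluggable ("W"), with
a half-cosine alternative. The printed first/second moment pair (0.999,
0.99) is preserved verbatim as the default even though it inverts the usual
convention; `conventional_moments = TRUE` swaps in (0.9, 0.999). The top
three checkpoints by validation accuracy are kept online (ties to the later
epoch) and can be evaluated individually or as a softmax-averaged ensemble
(`evaluate_checkpoints()`), including the mean softmax confidence of correct
predictions.

Patches are augmented (`augment_patch()`) by zero-padding `32^3 -> 36^3` at
uniform offsets, random `32^3` re-cropping, width-axis flipping with
probability 1/2, and a cutout (one axis-aligned cuboid, sides uniform in
4–8 voxels, filled with 0 after normalization, applied with probability 1/2).
Cutout geometry is unstated in the source recipe; these values are the
package's fixed choice and are exposed as arguments. The RNG draw order is
documented and is part of the reproducibility contract.

Intensity normalization clips to [-1000, 400] HU (air to bone) and min-max
scales to [0, 1]; patch regions outside the volume are padded with the
volume minimum (air-equivalent) *before* normalization so they map to the
window floor rather than to spurious bright borders.

## The phantom generator

`phantom_spec()` / `phantom_case()` emulate the aspects of nodule CT that the
pipeline depends on: an air-like background at -900 HU with additive Gaussian
noise (sigma 40 HU), and one embedded nodule per volume whose class differs
by size, contrast, and margin. Benign nodules are smooth ellipsoids with
semi-axes 2–4 mm and +200 HU contrast; malignant nodules have semi-axes
5–8 mm, +400 HU contrast, and 8 radial spicules (line segments, 2–5 mm, core
intensity) mimicking the margin irregularity radiologists weight. Volumes
default to `64^3` at 1 mm isotropic spacing — large enough that `32^3` patch
extraction, world/voxel geometry, and MetaImage round-trips are exercised
exactly as with full-size CT. Each case is deterministic in
`(rng_seed, class, index)`, and each writes LUNA16-dialect annotations with
synthetic ratings consistent with its class (benign mean < 3,
malignant > 3).

What the phantoms do *not* emulate: lung anatomy and vasculature, partial
volume and reconstruction-kernel effects, non-solid/ground-glass textures,
and inter-reader disagreement. Passing tests therefore demonstrate that the
machinery — geometry, labelling, optimization, saliency — behaves correctly
on data with a known, recoverable signal; they say nothing about clinical
accuracy on real CT, which requires the real accession and full-scale
training.

## Desk-scale study sizes

The shipped studies are sized to run on one CPU core:

- the end-to-end smoke trains the width-reduced 50-layer ghost genotype
  (widths 4/8/16/32) for 20 epochs on 40 phantoms (stratified 80/10/10),
  reaching ≥90% validation accuracy in a few minutes; it uses learning rate
  1e-3 with the conventional moments, the sane optimizer setting at this
  tiny scale (the full-scale recipe remains the package default);
- the saliency localization study trains a tiny shallow classifier (stem +
  one basic ghost block, 8 base channels, 25 epochs) on 60 phantoms and
  scores Grad-CAM++ against occlusion sensitivity on 20 held-out malignant
  cases;
- the separability guarantee fits a logistic model on two hand features
  (mask volume, mask mean intensity) over 100 phantoms, ensuring the smoke
  test's signal actually exists in the data.

## Grad-CAM++ in 3D

`grad_cam_pp()` computes class-discriminative saliency at any internal node.
The score is the *pre-softmax logit* of the target class: the closed form
assumes an exponential link between score and class evidence, under which the
second- and third-order terms reduce to expressions in the first-order
gradient `g = dS/dA` alone — no nested autodiff:

```
alpha = g^2 / (2 g^2 + sum_vox(A) g^3)
w_k   = sum_vox(alpha * relu(g))
cam   = relu(sum_k w_k A_k), then min-max normalized
```

Maps are normalized after trilinear upsampling (`upsample_cam()`; both orders
are available, normalization is idempotent and tested as such), rendered as
per-slice jet overlays and a 4×8 mosaic (`overlay_slices()`), and exportable
as MetaImage for external viewers. A layer disconnected from the score
yields an identically-zero map flagged `degenerate` rather than a normalized
artifact.

For the deep flagship network the default layer is the output of the last
block of stage 3, the conventional choice for this family. For the phantom
localization study the package uses its tiny shallow classifier (stem + one
basic ghost block at 8 base channels) trained to full convergence and reads
the map at the final block's features — the tiny net's own "last conv
block", at half resolution. Convergence matters here: under-trained or wider
variants of the study net yield boundary-dominated features whose saliency
argmax straddles the nodule surface and makes mask membership a coin flip,
while the narrow, fully converged net concentrates class evidence in the
nodule interior. The study's independent check, occlusion sensitivity
(`occlusion_map()`, logit drop under a sliding air-filled cube), localizes
the same evidence on the same inputs.

## Numerical and design notes

- Normalization uses eps 1e-5; batch norm keeps running statistics with
  momentum 0.1 and unbiased variance, and in eval mode backward reduces to a
  per-channel scaling (needed so saliency works on eval-mode models).
- Rating aggregation across readers is the arithmetic mean compared to 3
  exactly (mean > 3 malignant, < 3 benign, = 3 excluded); median is
  available. Duplicate annotations of one physical nodule (same series,
  centers within half the larger diameter) merge by union-find, ratings
  concatenated — the tests check this against a brute-force transitive
  closure.
- `world_to_voxel()` rounds to the nearest voxel and returns a zero-based
  (z, y, x) index, the ITK convention; arrays are (z, y, x) and world
  coordinates (x, y, z) mm, with the reorder confined to that one function.
- Argmax tie-breaks in prediction are "first index", making evaluation a
  pure function of weights and inputs even for the zero-initialized
  untrained head.
- Rendered percentages and million/Gmac figures round half-up to 2 dp.
- Metrics with zero denominators are reported `NA` and flagged, never 0.

## Known limitations

Training is CPU-bound R/Rcpp: practical for the desk-scale studies above,
not for full-scale runs over the real accession (a 200-epoch, ~800-nodule
run is a GPU-framework job; the data plumbing here — MetaImage, LUNA16 CSV,
LIDC-style XML, splits — is format-compatible with such a run). Mixed
precision, multi-GPU, and pretrained-weight loading are out of scope. The
MetaImage reader supports the uncompressed scalar types the pipeline writes
(short/float/double); compressed or tensor-valued MetaImage is not
supported.
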