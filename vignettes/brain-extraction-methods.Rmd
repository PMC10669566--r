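---
title: "Multi-view hybrid U-Net brain extraction: models and methods"
author: "brainext"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view hybrid U-Net brain extraction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Brain extraction (skull stripping) removes scalp, skull, dura and other
non-brain tissue from a head MRI, leaving a binary brain mask. It is the
first step of almost every neuroimaging pipeline, and errors made here
propagate into everything downstream. Fully 3D convolutional networks
segment head volumes well but are expensive in memory and computation;
plain 2D networks are cheap but degrade near the edges of the brain, where
slices contain little brain tissue. `brainext` implements a 2D pipeline
that closes most of that gap with three ingredients:

1. **K-means amplitude compression.** Each volume's voxel intensities are
   clustered into six groups (the conventional six-class decomposition of
   a head image: background, scalp/fat, skull, CSF, gray matter, white
   matter) and every voxel is replaced by its cluster centroid. Tissue
   gray levels are compressed onto a handful of plateaus, which removes
   within-tissue amplitude variation that a local convolution window
   cannot see past, and groups low-amplitude background noise into one
   class.
2. **Hybrid two-input 2D U-Nets.** Alongside the clustered image, each
   network receives the per-slice 2D gradient-magnitude map, which
   carries the local gray-level trend. Three wirings are provided (below).
3. **Brain-fraction-weighted multi-view fusion.** The volume is sliced
   along the three orthogonal anatomical planes, segmented per plane, and
   the three probability volumes are combined per voxel with weights
   proportional to each plane's predicted brain fraction in the slice
   through that voxel. A voxel sitting in an edge slice of one plane
   typically sits in a brain-rich slice of another; the fusion lets the
   plane that sees more brain dominate.

## Model

### Backbone

Every network is a classic 2D U-Net: per encoder level, two 3x3
convolutions with ReLU followed by 2x2 max pooling; channel width doubles
per level from `base_channels` (default 16) over `depth` levels (default
4); the decoder mirrors the encoder with 2x2 transposed-convolution
upsampling and skip connections; a final 1x1 convolution feeds a 2-class
softmax over brain / non-brain. Slices whose side is not a multiple of
`2^depth` are reflect-padded and the outputs cropped back.

### Hybrid variants

* `single` — one input image, plain U-Net.
* `hybrid1` — the two input images are concatenated channel-wise at the
  input layer only; one standard U-Net follows. This is the conventional
  multi-input arrangement.
* `hybrid2` — two independent encoders, one per input; their deepest
  feature maps are concatenated and a **single decoder** upsamples, with
  each skip connection taking both encoders' same-level features.
* `hybrid3` — two complete U-Nets, one per input, cross-connected at
  every level: each encoder block past the first consumes both networks'
  pooled features, and each decoder block consumes four maps (both
  networks' upsampled features and both skip connections). The two decoder
  outputs are concatenated before the final classification layer.

Trainable-parameter counts are strictly ordered
`hybrid3 > hybrid2 > hybrid1 > single` at any depth and width, which the
test suite checks by exact enumeration. The channel bookkeeping of
`hybrid3` (own-features-first concatenation order at every merge) is a
package decision; only the merge topology is prescribed by the design.

### Fusion rule

For per-plane brain-probability volumes $P_1, P_2, P_3$ the fused volume
is the per-voxel convex combination

$$P_c = w_1 P_1 + w_2 P_2 + w_3 P_3,$$

where for voxel $(i, j, k)$ the raw weights are the sagittal slice-$i$,
coronal slice-$j$ and transverse slice-$k$ predicted brain fractions
(fraction of voxels with probability at least 0.5), normalized per voxel
to sum to one. Three decisions deserve a note:

* **Weights come from predictions, not labels.** Ground truth is not
  available at inference, so each plane's own thresholded prediction
  supplies its slice fractions.
* **Per-voxel normalization.** Normalizing per voxel (rather than once
  per volume) is what makes the plane with a relatively higher brain
  proportion dominate for that particular voxel; with per-volume weights
  an edge slice of a weak plane would still carry its full weight
  everywhere.
* **Empty-region fallback.** Where all three fractions are zero the
  weights are set to 1/3 each; the fused probability is then the plain
  average, and thresholding still yields background.

The final mask is `fused probability >= 0.5`, with the tie at exactly 0.5
counted as brain (documented and tested). Fusion accepts two planes (same
normalization) and degenerates to the identity for one.

## Training engine

No deep-learning framework is used: the package ships a compact CPU
engine — GEMM-based 3x3 convolution kernels (im2col + BLAS, single
precision internally), 2x2 max-pool and transposed-convolution layers, and
a minimal reverse-mode tape — with Adam (learning rate `1e-3`) minimizing
mean pixelwise cross-entropy. Cross-entropy is the standard U-Net choice;
an edge-weighted loss was considered and rejected because its weight
scales are data-sensitive. Weight init is He-style, deterministic per
seed; shuffling is driven by the training seed, so a run is exactly
reproducible on one machine/BLAS configuration. Training keeps the
weights of the epoch with the lowest training loss. Convolution
arithmetic runs in float32 (parameters stay double); at these network
sizes the rounding is far below the noise of stochastic training.

## Preprocessing details

* K-means is fitted **per volume** (not pooled across subjects) so
  centroids track each scan's intensity scale; at inference a fresh model
  is fitted for the incoming volume. Pooling across subjects would need
  inter-scan intensity standardization, which is out of scope.
* Clustering runs Lloyd iterations (cap 300) from several candidate
  initializations — a near-exact binned 1D dynamic program plus k-means++
  restarts, all derived from one seed — keeping the lowest inertia.
  Head-amplitude histograms are dominated by background, and k-means++
  alone occasionally locks onto a local optimum that splits background
  and merges two tissues; the dynamic-program seed (1D clusters are
  contiguous in sorted order, so the problem is exactly solvable on a
  weighted histogram) removes that failure mode deterministically.
* Background voxels are included: grouping low-amplitude noise is part of
  the motivation for clustering.
* The remap replaces each voxel by its nearest centroid, ties to the
  lower centroid; it is idempotent, monotone and never increases the
  number of distinct values. A `label` output mode gives cluster indices
  instead of centroid intensities for experimentation.
* Gradient maps are 3x3 Sobel magnitudes per slice (replicate-padded),
  min-max scaled to [0, 1] per volume, and are computed from the
  **preprocessed** image by default (a `raw` switch exists); a
  central-difference operator is available by configuration.

## The phantom generator

`generate_phantom()` builds the simplest object that exercises every
mechanism above: nested ellipsoids (white-matter core, gray-matter shell,
thin CSF rim — their union is the brain mask) wrapped in skull and scalp
shells over background, with additive Gaussian noise. The brain ellipsoid
is slightly off-center, so per-plane slice brain-fraction curves are
asymmetric and unimodal, with near-empty edge slices — the regime in which
2D segmentation degrades and fusion should help. `generate_cohort()`
jitters axes, tissue means, noise and offset to stand in for a
multi-subject dataset, and `crossval_folds()` splits by subject (never by
slice, to avoid leakage).

Defaults: six tissue means spaced 20 intensity units apart and noise
sigma 2, i.e. a minimum contrast-to-noise ratio (CNR, minimum
inter-tissue gap over sigma) of 10. We define the phantom's "SNR" as this
CNR. The default was chosen so the six-class clustering is well-posed:
because the background class dominates the voxel count, K-means at CNR 5
already prefers splitting background and merging skull with CSF — a
property of the objective, not a bug — and a default that makes the
canonical six-cluster decomposition recoverable is the right baseline.
A hard preset (sigma around 10, gap about 2 sigma) stress-tests that
degeneracy deliberately.

What the phantom does **not** emulate: anatomy (gyri, ventricles),
partial-volume mixing, bias fields, Rician noise. Passing tests on
phantoms therefore verifies the mechanisms — clustering recovery,
architecture wiring, fusion arithmetic, the fraction/accuracy
relationship — not clinical-grade performance on real scans.

## Evaluation

`evaluate()` reports Dice `2TP/(2TP+FN+FP)`, sensitivity `TP/(TP+FN)` and
specificity `TN/(TN+FP)` from voxel confusion counts. Degenerate
denominators (empty phantom corners) use documented conventions: both
masks empty gives Dice and sensitivity 1; specificity is 1 when `FP = 0`
and `TN > 0`. `slice_profile()` reports, per slice along a plane, the
true brain fraction and the per-slice F1, with F1 = 1 for slices empty in
both masks (the profile's purpose is ranking slices by difficulty, and an
empty slice predicted empty is a perfect answer). The CLI prints scores
as percentages with two decimals.

## Problem sizes used by the test suite

The package's correctness surface is validated at desk scale, chosen as
the smallest sizes at which every mechanism is exercised end-to-end:

* unit tests use 24-cube phantoms and depth-2/width-4..8 networks;
* the end-to-end recovery and ablation harness uses 10-subject cohorts of
  32-cube phantoms (brain semi-axes about 8.5 x 7.75 x 8 voxels), an
  8-train / 2-held-out split, and the full-architecture networks
  (depth 4, base 16) trained for 18 epochs with Adam 1e-3, batch 16, on
  every third slice per plane (training loss plateaus well before this);
  medians are taken over three cohort seeds.

Training on a slice subset is a deliberate scale choice: adjacent phantom
slices are highly redundant, and prediction always uses every slice.

## Known limitations

* The engine is CPU-only and single-image-at-a-time; it is written for
  method verification and small studies, not high-throughput inference.
* Per-volume K-means assumes the six-class intensity structure is at
  least approximately present; lesions, infants or strong bias fields
  violate this and would need a different preprocessing choice.
* Orientation handling trusts the NIfTI header when present (volumes are
  reoriented to the canonical sagittal/coronal/transverse axis order) and
  otherwise takes the stored axis order as canonical; oblique
  acquisitions are not resliced.
* Fusion weights are computed, not learned; learned fusion is explicitly
  out of scope.
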