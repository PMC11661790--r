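---
title: "tomoseg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tomoseg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

tomoseg is a headless toolkit for semantic segmentation of cryo-electron
tomography (cryoET) volumes and for the two downstream steps that
segmentation usually feeds: particle picking for subtomogram averaging, and
mesh export for visualization and measurement. This vignette explains the
models and procedures the package implements, the tunable parameters and
their defaults, the numerical choices, and what the synthetic phantom tests
do and do not demonstrate about real data.

## The segmentation model

Tomograms are large, low-contrast 3D volumes; annotation budgets are tiny.
The package therefore follows the patch-based recipe that has proven
effective in interactive cryoET segmentation tools: the user marks a handful
of 64 x 64 pixel boxes on individual z-slices, each either *positive* (a
binary label mask painted over the feature) or *negative* (the feature is
absent; the box may well contain other confusable structures), and a compact
2D convolutional network is trained per feature to map a patch to a
per-pixel probability.

Working slice-wise with 2D networks rather than 3D ones is a deliberate
trade: annotation is naturally 2D, training sets of a few dozen boxes are
far too small to constrain 3D kernels, and slice-wise inference parallelises
trivially over a tomogram. The cost is that predictions carry no explicit
z-context; the interaction algebra below recovers some 3D coherence.

### From sparse boxes to a training set

`extract_boxes()` crops each annotated box from its slice. Two details
matter:

* **Edge clamping.** A center closer than half a box to the slice edge is
  shifted inward so the crop fits; boxes are never silently dropped, and
  each shift is reported. Labels travel with the box unchanged.
* **Per-patch normalization.** Each image patch is standardized to zero
  mean and unit variance (`(x - mean) / sd`, with a 1e-9 floor on the
  standard deviation; an exactly flat patch becomes all zeros). This makes
  the network insensitive to the wildly varying absolute intensity scales
  of reconstructed tomograms, and the identical transform is applied to
  every tile at inference time.

`resample_training_set()` then balances and augments: every positive patch
is emitted 10 times, negatives are drawn uniformly **with replacement**
from the negative pool until the emitted negative:positive ratio is 1.3:1
(count rounded half-up), every emitted patch gets a random orientation, and
the order is shuffled — all reproducibly from one seed. The copies, ratio
and patch size defaults reproduce a training protocol in routine use for
this class of data.

Random orientation is realized as the 8 dihedral transforms of the square
(4 quarter-turn rotations x optional flip) rather than arbitrary-angle
rotation: dihedral transforms are exact on the pixel lattice, so binary
label masks pass through without interpolation artifacts, and image/label
pairs stay perfectly aligned. The emitted *positive* multiset is therefore
independent of the seed (only orientations and order change), which the
test suite checks with an orientation-invariant checksum.

### Architectures

`build_model()` instantiates one of the registered architectures:

* `eman2` — a shallow 3-conv encoder–decoder (8 filters, one 2x pooling
  stage), in the spirit of the compact default networks of general EM
  suites. Fast enough to train in minutes on a CPU; the reference
  architecture for the package's own recovery experiments.
* `vgg` — a VGG-style double-conv stack (16/32 filters, one pooling
  stage).
* `unet` — a two-level U-Net with skip connections (8/16/32 filters).

All are built from the same small layer vocabulary (3x3 same-padded
convolutions, 2x2 max pooling, 2x nearest-neighbour upsampling, channel
concatenation) and end in a sigmoid convolution, so **every prediction is
in [0, 1] by construction**. `count_parameters()` reports trainable weight
counts, which is the rough proxy for compute cost a user chooses a network
by.

The registry is open: `register_architecture()` adds a design at runtime,
and `load_architecture_plugins(dir)` sources every `.R` file in a directory
that defines an `architecture` list (`name`, `downsample_factor`,
`build(box_size)`), mirroring the drop-a-file plugin convention of the
interactive tools this package is patterned on. The layer kernels
(im2col + GEMM convolutions with full backpropagation, pooling,
upsampling, Adam) are implemented in the package's own C++ because no deep
learning framework is assumed; the engine is deliberately minimal and
fully deterministic given seeds.

### Training

`train_model()` minimizes pixel-wise binary cross-entropy with Adam
(learning rate 1e-3 by default; the loss is computed on logits for
stability). The default protocol is 50 epochs at 32 images per batch with
**no validation split**: with only tens of unique annotated boxes, holding
out patches costs more in training signal than it buys in monitoring, so
the per-epoch history records training losses. Setting
`validation_split > 0` switches the history to held-out losses; use it when
the annotation set grows. Training aborts with a diagnostic naming the
epoch if the loss ever becomes non-finite.

### Slice-wise inference

`segment_volume()` tiles every z-slice with `box_size` patches on a stride
grid (default half-box, plus a flush tile at each far edge), normalizes
each tile, predicts, and **averages** overlapping predictions. Averaging
was chosen over margin-cropping for stitching because it is insensitive to
the exact receptive field of whichever architecture is in use; the seams it
leaves are below the decision threshold in practice. Slices smaller than
the box are reflectively padded and cropped back. Constant inputs map to
identical outputs regardless of their level (a direct consequence of
per-patch normalization), which the tests use as a shift-invariance check.

## The interaction algebra

Independent per-feature models make correlated mistakes: membrane models
fire on carbon-film edges, particle models fire on membranes. The package
implements two conditional suppression mechanisms that operate purely on
prediction volumes:

* **Interactions** (`apply_interaction()`): a binary mask is made by
  thresholding the *parent* feature's predictions; the mask is dilated by a
  disk of radius R (the *interaction radius*, given in nm); the *child's*
  predictions are multiplied by the mask (**colocalize**) or its complement
  (**avoid**).
* **Competition** (`apply_competition()`): per voxel, every *absorbing*
  feature is zeroed wherever any other *emitting* feature's prediction is
  strictly higher. A feature may emit and absorb simultaneously.

Design choices worth spelling out:

* **2D disks, per slice.** The kernel is circular and applied within each
  z-slice, consistent with slice-wise segmentation; a `kernel_3d` flag
  switches to a spherical kernel. Dilation is implemented as a Euclidean
  distance transform of the mask thresholded at R, so the result is exactly
  "all voxels within R of a mask voxel" — the same definition a brute-force
  distance check uses, which makes the oracle tests exact rather than
  approximate.
* **Units.** R converts to pixels as `round(R_nm * 10 / pixel_size_A)`,
  rounding half-up; a radius that resolves to 0 px means no dilation and is
  reported. Mask inclusion uses `>=` at the threshold.
* **Avoidance convention.** The mask recipe literally describes
  colocalization; for avoidance the package multiplies by the complement
  of the *dilated* mask (suppress everything within R of the parent). The
  alternative reading — dilate the complement, i.e. keep everything within
  R of non-parent — differs in a band of width R at mask borders and is
  available via `avoid_mode = "complement_before"`.
* **Simultaneous competition.** All comparisons use the original input
  values, so the result is independent of feature order and applying
  competition twice changes nothing. Ties preserve both features
  (suppression requires *strictly* higher).
* **Composition order.** `apply_pipeline()` applies competition first, then
  the interactions in list order, each seeing the current state. Order
  matters exactly when an interaction edits a feature that a later
  interaction uses as parent — the canonical "membrane avoids carbon, then
  particle colocalizes with membrane" chain relies on this.

Both mechanisms are *suppression-only*: outputs never exceed inputs
voxel-wise, colocalization output grows monotonically with R, avoidance
shrinks monotonically — all verified as properties in the test suite.

The package's reference use of the algebra is isolating membrane-bound
platform particles that sit at a fixed ~22 nm offset from the membrane
surface: `avoid(membrane, R = 10 nm)` removes false positives painted on
the membrane itself, then `colocalize(membrane, R = 30 nm)` removes
everything not in the membrane's vicinity; what survives is the band that
contains the platforms.

## Particle picking

`pick_particles()` converts a prediction volume into coordinates in six
steps:

1. Threshold at a user-specified level.
2. Compute the 3D Euclidean distance transform of the foreground (distance
   to the nearest zero voxel), via an exact separable algorithm on squared
   distances (integers, so equality comparisons are exact).
3. Watershed the negated distance transform, seeded at its local maxima:
   priority-flood with a max-heap, 26-connected, insertion-order FIFO on
   ties, so results are deterministic. A plateau of equal distance values
   contributes a single seed (its minimum voxel index). Every foreground
   voxel is assigned to exactly one group; the groups partition the
   foreground.
4. Discard groups smaller than a minimum volume, converted from nm^3 using
   the voxel size ("dust").
5. Weight each group by the sum of its prediction values; visit groups in
   descending weight (ties broken by ascending centroid, lexicographically)
   and keep a group only if its centroid is at least the minimum spacing
   from every centroid already kept. The greedy highest-weight-first order
   resolves the chain ambiguity in pairwise "discard the lighter one"
   rules; spacing is measured centroid-to-centroid.
6. Report each kept group's unweighted voxel centroid, rounded half-up to
   integer voxel coordinates, sorted by descending weight.

On volumes where every connected component contains a single
distance-maximum plateau, watershed grouping reduces to connected-component
labelling — the test suite checks exact membership agreement against an
independent brute-force labeller on dozens of random sphere volumes, and
that touching-sphere "dumbbells" are split in two at the neck.

Coordinates are 0-based voxel indices `(x, y, z)` throughout; since some
extraction tools index from 1, `write_particles()` has a `one_based` flag.

## Meshing

`volume_to_mesh()` extracts the isosurface by **marching tetrahedra**: each
grid cell is split into six tetrahedra around a fixed body diagonal, so
adjacent cells share face diagonals and the surface is watertight; vertices
are placed by linear interpolation along tetrahedron edges and welded by
the exact identity of the grid edge they lie on, making topological
quantities (Euler characteristic, surface component counts) exact rather
than tolerance-dependent. Marching tetrahedra was preferred over classic
marching cubes because it needs no 256-case lookup table, has no ambiguous
configurations, and guarantees a closed 2-manifold on the cell
decomposition — at the cost of roughly twice the triangle count, which is
irrelevant at the volumes involved. Triangles are consistently wound with
normals pointing away from the high-valued interior; vertices are scaled to
Angstrom with the voxel size and origin.

One sampling note: isosurface extraction assumes a *sampled continuous
field*. On hard 0/1 volumes every crossing lands mid-edge and the surface
is systematically too large (about +28% for a digitized sphere); with even
a 1-voxel linear ramp at feature boundaries the area of a radius-10 sphere
mesh is within a fraction of a percent of 4*pi*r^2. The accuracy tests
therefore sample spheres with a 2-voxel ramp, which is the construction a
band-limited imaging system would produce anyway.

`filter_dust()` removes connected components (26-connected, matching
picking) below a minimum physical volume before meshing or display,
leaving retained components bit-identical.

## The phantom generator

`generate_phantom()` builds tomogram-like test volumes with per-feature
binary ground truth so that training, interactions, picking and meshing
are all testable without external data. The scene vocabulary:

* **membranes** — spherical shells, default radius 10–16 nm, 5 nm thick
  (small liposomes);
* **carbon** — an optional half-space slab with a straight edge covering
  part of the field of view, the lacey-film analogue; objects are placed
  clear of it;
* **platforms** — small discs held at a fixed offset (default 22 nm)
  outside a membrane surface, the membrane-bound antibody-platform
  analogue. Their direction vectors are sampled in the xy-plane: the
  interaction algebra acts per-slice, so the membrane–platform offset is
  an in-plane quantity, just as membrane side views dominate real
  tomograms;
* **granules** — solid spheres (6–9 nm), the generic globular particle;
* **filaments** — thin cylinders at mostly in-plane angles;
* plus additive Gaussian noise (default sigma 0.3 against a
  feature/background contrast of 1, i.e. a visibly noisy but workable
  SNR ~3), an optional z-only Gaussian blur to mimic anisotropic
  resolution, and a contrast-inversion flag for the opposite display
  convention.

Objects are placed by rejection sampling with explicit no-overlap margins
(bounded retries, then an error naming the constraint), features are
mutually disjoint, and everything is reproducible from one seed.
`object_bounds` restricts placement to a sub-box — used to emulate the
common situation where part of the field of view is feature-free, and to
guarantee eligible centers for negative annotation boxes.

`generate_training_boxes()` samples positive boxes on random foreground
voxels (ground-truth crops as labels) and negative boxes at least one box
width (3D Euclidean, configurable) from any foreground voxel — negatives
may freely contain *other* features, as real negative annotations do.

**What the phantom does not emulate** — and hence what passing tests do and
do not show: there is no contrast transfer function, no missing-wedge
artifacts by default, no dose-dependent noise correlation, and no
biological texture; features are homogeneous-density solids. Recovery
results on phantoms (e.g. the IoU ~0.9 granule experiment below)
demonstrate that the training/inference machinery is correct and that the
pipeline composes properly; they say nothing about segmentation accuracy
on real tomograms, which depends on annotation quality and feature
contrast.

## Problem sizes and runtime choices

The package's own recovery experiment — chosen to exercise the full
standard protocol at a size a laptop CPU handles in minutes — trains the
shallow `eman2` network for 50 epochs, batch 32, on ~500 resampled 64 x 64
patches (22 positive and 30 negative boxes from a 192 x 192 x 48 granule
phantom at 10 A/voxel, noise sigma 0.3), then segments a second,
held-out phantom with stride-32 tiling and scores voxel IoU at threshold
0.5 against ground truth. This configuration reaches IoU ~0.9, with ~0.8
as the pass line to absorb seed-to-seed variation. Property checks
(picking-vs-oracle, interaction-vs-oracle) use dozens of random volumes at
<= 32^3, where brute-force oracles are exact and fast.

## Known limitations

* 2D slice-wise networks: no learned z-context (the interaction algebra
  and 3D picking recover some, but a true 3D network is out of scope).
* The CNN engine is CPU-only and double-precision; it is built for
  correctness, determinism, and small models, not for large-scale GPU
  training.
* Interactions assume isotropic pixels within a slice; anisotropic input
  voxel sizes fall back to the x spacing with a warning.
* The adversarial (pix2pix-class) architecture family is not included;
  the plugin mechanism is the extension point for such designs.
* `suppress_close_groups()` is greedy by weight; a globally optimal
  maximum-weight spacing-respecting subset is NP-hard and not attempted.
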