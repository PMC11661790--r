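# tomoseg

Headless CNN segmentation, model interactions and particle picking for
cryo-electron tomography (cryoET), in R.

Segmentation — assigning per-voxel probabilities to features such as
membranes, ribosomes or filaments — is the step that stands between a
reconstructed tomogram and almost every downstream analysis: picking
subtomogram coordinates for averaging, or building 3D feature maps of
cellular architecture. tomoseg implements that workflow as a scriptable,
batch-oriented library for people who process many tomograms at a time:
annotate a few boxes, train a compact per-feature CNN, segment volumes
slice-wise, clean up multi-feature predictions with a conditional mask
algebra, then pick particles or export meshes. All interchange uses the
field's standard formats: MRC2014 volumes, tab-separated / STAR particle
coordinates, Wavefront OBJ meshes.

## What is inside

* **Annotation → training set** (`annotation_boxes`, `extract_boxes`,
  `resample_training_set`): 64×64 boxes with binary label masks; per-patch
  standardisation; positives copied 10×, negatives resampled to a 1.3:1
  ratio, dihedral (rotation/flip) augmentation, all seeded.
* **Model zoo** (`build_model`, `train_model`, `segment_volume`): shallow
  encoder–decoder (`eman2`), VGG-style stack (`vgg`) and U-Net (`unet`)
  architectures built on the package's own deterministic conv/pool/upsample
  engine (C++, im2col + GEMM, Adam, pixel-wise binary cross-entropy
  `L = -mean[y log p + (1-y) log(1-p)]`); default protocol 50 epochs,
  batch 32, no validation split. Drop-in architecture plugins via
  `register_architecture()` / `load_architecture_plugins()`.
* **Model interactions** (`apply_interaction`, `apply_competition`,
  `apply_pipeline`): *colocalize* keeps child predictions within the
  interaction radius R of a thresholded parent (the parent mask is dilated
  with a circular kernel, `R_px = round(R_nm · 10 / pixel_size)`);
  *avoid* multiplies by the complement; *competition* zeroes an absorbing
  feature wherever any emitting feature's prediction is strictly higher
  (simultaneous, order-free semantics).
* **Particle picking** (`pick_particles`): threshold → exact 3D Euclidean
  distance transform → watershed seeded at distance maxima → minimum-volume
  ("dust") filter → weight-ordered minimum-spacing suppression → integer
  centroids, weights = summed prediction values.
* **Meshing** (`volume_to_mesh`, `filter_dust`): watertight marching-
  tetrahedra isosurfaces with exactly welded vertices, vertices in Å.
* **Phantoms** (`generate_phantom`, `generate_training_boxes`): synthetic
  tomograms — vesicle membranes, a carbon-film slab, membrane-bound
  platforms at a fixed 22 nm offset, granules, filaments, Gaussian noise —
  with per-feature ground truth, so the whole pipeline is testable offline.
* **CLI** (`inst/cli/tomoseg`, `run_batch_segment`): `train`, `segment`,
  `pick`, `mesh`, `phantom` subcommands with YAML pipeline configs, for
  batch jobs over many tomograms.

Coordinates are 0-based voxels `(x, y, z)` with `z` the slice index
(`one_based = TRUE` on write for tools that expect 1-based).

## Worked example

Train a granule (globular particle) detector on one synthetic tomogram and
pick particles on a held-out one:

```r
library(tomoseg)

# a synthetic tomogram: 6 granules in a noisy 128×128×40 volume, 10 Å/voxel
ph <- generate_phantom(phantom_config(
  shape = c(40, 128, 128), pixel_size = 10,
  n_vesicles = 0, n_granules = 6, noise_sigma = 0.3, seed = 42,
  object_bounds = c(0, 0.6, 0, 1, 0, 1)))

# "annotate" 15 positive and 20 negative 32×32 boxes from ground truth
boxes <- generate_training_boxes(ph, "granule", n_pos = 15, n_neg = 20,
                                 seed = 1, box_size = 32)
ts <- resample_training_set(extract_boxes(ph$volume, boxes, box_size = 32),
                            copies = 10, neg_ratio = 1.3, seed = 1,
                            feature_name = "granule")
print(ts)
#> <training_set> 'granule': 345 patches (150 pos, 195 neg), 32x32 px @ 10 A/px

model <- build_model("eman2", box_size = 32, seed = 1,
                     feature_name = "granule")
model <- train_model(model, ts, train_config(epochs = 15, batch_size = 32,
                                             seed = 2))
glance(model)
#> # A tibble: 1 × 5
#>   arch_name box_size n_parameters epochs final_loss
#>   <chr>        <dbl>        <int>  <int>      <dbl>
#> 1 eman2           32          737     15     0.0302

# segment a held-out phantom, score against ground truth, pick particles
ph2 <- generate_phantom(phantom_config(
  shape = c(40, 128, 128), pixel_size = 10,
  n_vesicles = 0, n_granules = 6, noise_sigma = 0.3, seed = 99,
  object_bounds = c(0, 0.6, 0, 1, 0, 1)))
pred <- segment_volume(model, ph2$volume, stride = 16)
gt <- ph2$ground_truth$granule$data > 0
sum(pred$data >= 0.5 & gt) / sum(pred$data >= 0.5 | gt)
#> [1] 0.835   # voxel IoU at threshold 0.5

particles <- pick_particles(pred, pick_config(threshold = 0.5,
                                              min_volume_nm3 = 50,
                                              min_spacing_nm = 10))
particles
#> # A tibble: 6 × 4
#>       x     y     z weight
#>   <int> <int> <int>  <dbl>
#> 1    17    84    30  2069.
#> 2    74    82    15  1932.
#> 3    15    19    12  1648.
#> 4    20    69    19  1591.
#> 5    13   100    21  1270.
#> 6    52    85    23  1204.
write_particles(particles, "granules.txt")  # x<TAB>y<TAB>z, one per line
```

All six planted granules are recovered (the phantom contains exactly six),
each reported at its blob centroid with a weight equal to the summed
prediction values — the quantity the spacing filter ranks particles by.

The loss curve is `autoplot(model)`; a slice with its prediction overlay is
`plot_slice(ph2$volume, z = 20, overlay = pred)`.

The same pipeline runs from a shell:

```sh
inst/cli/tomoseg phantom --config phantom.yaml --out-dir fx/
inst/cli/tomoseg segment --models m1,m2 --volumes fx/ --config pipe.yaml --out-dir seg/
inst/cli/tomoseg pick --in seg/volume_granule.mrc --threshold 0.5 \
    --min-volume 50 --min-spacing 10 --out granules.txt
inst/cli/tomoseg mesh --in seg/volume_granule.mrc --iso 0.5 --min-dust 50 \
    --out granule.obj
```

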