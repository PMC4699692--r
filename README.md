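# volseg

A headless, scriptable segmentation engine for volumetric light- and
electron-microscopy datasets, written in R with compiled cores for the
heavy primitives. It targets the common organelle-segmentation workflow on
3-D/4-D stacks: load calibrated volumes, preprocess, combine manual-style
and semiautomatic operators, polish by quantification filtering, and export
models and measurement tables — all from scripts, with a logged, replayable
history.

The package is organized around a four-layer data model — **Image** (raw
data), **Selection** (the active binary working layer), **Mask** (an
optional staging/restriction layer), and **Model** (the final
multi-material label volume) — sharing one physical geometry (voxel size,
bounding box, X:Y:Color:Z or X:Y:Color:Time axes) that every spatial
transform keeps consistent.

Core methods:

* **Preprocessing** — per-slice intensity normalization (whole-slice or
  masked-area), Perona–Malik anisotropic diffusion, grayscale/binary
  morphology, spacing-aware gradient magnitude, multiscale Frangi
  vesselness (2-D, 3-D, or sequential XY/ZX planes), all restrictable to
  rectangular/elliptic/polygonal ROIs.
* **Manual-tool equivalents** — brush (plain and against superpixels),
  spot and anisotropy-corrected 3-D ball, magic wand, region growing,
  membrane click tracking by shortest-path search, 3-D line tracking in
  physical coordinates, morphological shape interpolation
  (signed-distance blending) and open-curve line interpolation between key
  slices, and inclusive black-and-white thresholding.
* **Semiautomatic engines** — SLIC superpixels/supervoxels in physical
  coordinates with region adjacency; interactive graph-cut
  (max-flow/min-cut with `w_ij = exp(-|mu_i - mu_j| / sigma)` n-links);
  marker-controlled priority-flood watershed on intensity, gradient, or
  arbitrary boundary reliefs; fused-object separation by anisotropy-aware
  exact Euclidean distance transform with h-maxima suppression; and two
  seeded random-forest classifiers (per-voxel membrane detection,
  per-supervoxel intensity classification).
* **Quantification** — 2-D/3-D connected-component tables (volume,
  eccentricity, Crofton perimeter, orientation, intensity statistics) in
  physical units, property-range filtering, per-material model smoothing,
  manual distance/angle/caliper/radius measurements with intensity
  profiles, CSV/TSV export.
* **Pipelines** — a YAML-serializable recipe runner with a per-step report
  and action logging, including a built-in 13-step workflow that segments
  a densely packed mitotic-cell volume into ER, lysosome, peroxisome,
  lipid-droplet, chromosome and mitochondrion materials, and an
  ER global-threshold + quantification-filtering workflow.
* **Fixtures** — seed-reproducible synthetic phantoms (blobs, tubular
  networks, membranes, nuclei, fused sphere pairs, and a composite
  mitotic-cell phantom) with ground truth, used throughout the tests.

I/O covers multipage TIFF, NRRD (with spacings), numbered PNG/TIFF series,
write-only ASCII AmiraMesh, dataset bundles with a plain-text YAML sidecar,
and translation-only stitching with FFT shift estimation.

## Worked example

Segment the nucleus of a membrane-bounded-organelle phantom in 3-D from
two marker scribbles on a single slice, then quantify it:

```r
library(volseg)

np <- make_nucleus_phantom(shape = c(96, 96, 96), radius = 30, seed = 32)
zc <- round(np$center[3])
seeds <- seed_labels(
  object     = matrix(c(round(np$center[1]), round(np$center[2]), zc), 1),
  background = rbind(c(4, 4, zc), c(92, 92, zc), c(4, 92, zc), c(92, 4, zc)),
  shape      = ds_dim(np$ds))

sw <- watershed_markered(np$ds, seeds, use_gradient = TRUE)
dice(sw$object, np$gt == 1)
#> [1] 0.9815536

lo <- label_objects(sw$object, "3d",
                    voxel_size = np$ds$geometry$voxel_size,
                    image = img3d(np$ds))
lo$table[, c("id", "n_voxels", "volume", "eccentricity", "int_mean")]
#>   id n_voxels volume eccentricity int_mean
#> 1  1   109015 109015   0.05058308 105.2762
```

The Dice coefficient of 0.98 against the planted ground truth shows the
two scribbles were enough to recover the organelle in 3-D; the object
table reports its size (in cubic physical units — here the phantom's
1 nm isotropic voxels), near-spherical shape (eccentricity 0.05), and
mean interior intensity of about 105 gray levels.

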