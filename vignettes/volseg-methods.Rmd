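---
title: "volseg: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{volseg: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`volseg` is a headless, scriptable segmentation engine for volumetric
light- and electron-microscopy data. This vignette explains the data model,
the segmentation operators and their parameters, the algorithmic and
numerical choices made where the design was genuinely open, what the
synthetic phantoms do and do not emulate, and the package's known
limitations. Everything quantitative claimed here is recomputed by the test
suite or by `scripts/acceptance.R`; this document states no number that the
code does not itself produce.

## The four-layer data model

A `LayeredDataset` couples one image volume with three annotation layers
that always share its spatial shape:

* **Image** — the raw grayscale or multichannel data, unsigned 8- or
  16-bit. Semantically the axis order is X:Y:Color:Z or X:Y:Color:Time;
  time-lapse data are treated as stacks of independent 3-D volumes for all
  segmentation operations.
* **Selection** — the binary working layer every interactive-style tool
  writes into.
* **Mask** — an optional second binary layer used to stage results and to
  restrict operations (masked thresholding, masked normalization).
* **Model** — the final multi-material segmentation, an 8-bit label field
  with a material table (unique contiguous ids from 1, unique names;
  0 is background everywhere).

A `VolumeGeometry` carries the voxel size (defaulting to nanometres, the
natural unit for EM), the physical coordinate of the dataset origin, and
the stack-axis semantics. Voxel `i` (0-based) is centred at
`bbox_min + (i + 0.5) * voxel_size`; this convention is applied uniformly
in measurements, distance transforms and interpolation. Every spatial
transform adjusts the geometry: cropping shifts the origin, resizing
rescales the voxel size so the physical extent is invariant, rotation and
transposition permute the voxel dimensions. Annotation layers are always
resampled nearest-neighbour — interpolating a label field would invent
labels.

Mutating operations append one record to an action log that serializes
with the dataset, so a processing history always travels with the data.
Undo is snapshot-based with independent, individually bounded 2-D (single
slice) and 3-D (whole layer) histories. Snapshots rather than diffs are a
deliberate simplicity-over-memory choice: headless batch use rarely needs
deep histories, and the depth is configurable per scope. Undoing with an
empty history is an explicit warning-and-no-op, never silent corruption.

Large volumes can be chopped into a grid of blocks (optionally
overlapping) whose cores tile the source exactly; each block carries
offset geometry and is a self-contained dataset. Reassembly is bit-exact
for unmodified blocks; where overlapping blocks disagree, the later block
in plan order wins — an arbitrary but documented precedence (any fixed
rule works, since overlaps exist only to give block-local operations
context). Material tables are reconciled by name on reassembly, with
labels remapped onto the union table.

## File formats and the sidecar

NRRD (raw and gzip encodings, uint8/uint16, little endian) is the
preferred interchange format because it is the only supported one that
carries voxel spacings natively; custom `key:=value` fields store the
bounding-box origin and units. Multipage TIFF and numbered PNG/TIFF series
are supported for interoperability; since neither PNG nor the TIFF writer
used here can embed physical resolution, dataset bundles
(`save_dataset()`) always write a plain-text YAML sidecar with the
geometry, material table and action log. On *reading* third-party TIFFs,
resolution tags are honored and converted into the dataset unit; when no
metadata exists the voxel size defaults to 1 with a logged warning — a
wrong-but-visible default being preferable to a silently wrong unit.
AmiraMesh output is a write-only ASCII uniform-lattice export with a
material section, for downstream rendering tools.

Stitching is translation-only by design: per-pair in-plane shifts are
estimated by FFT cross-correlation of mean projections (or given
manually), the moving dataset's bounding box is adjusted, and both are
painted onto the union grid with the fixed dataset winning overlaps.
Richer (rotational, elastic) registration is out of scope.

## Preprocessing filters

**Slice normalization** removes slice-to-slice intensity fluctuation
(common in serial block-face series) by linearly rescaling each slice to
the dataset-wide mean and standard deviation. The target is the *global*
statistic rather than the first slice so the result is independent of
slice order. The masked mode computes both the per-slice and the target
statistics over masked voxels only, which equalizes stacks whose content
differs but whose background is comparable.

**Anisotropic diffusion** is the Perona–Malik scheme: per iteration each
voxel moves by `lambda * sum(g(dI) * dI)` over its 4-neighbour (2-D,
default) or 6-neighbour (3-D) differences, with conductance
`g(d) = exp(-(d/kappa)^2)` (default; favors high-contrast edges) or the
rational variant. `lambda` is capped at 0.25, the 2-D stability limit.
`kappa` is in intensity units: gradients well above it barely diffuse, so
edges survive while flat-region noise is averaged away. Defaults
(`iterations = 10`, `kappa = 20`, `lambda = 0.25`, per-slice) suit 8-bit
EM data with moderate noise.

**Morphology** uses flat structuring elements (disk in 2-D, ball in 3-D)
over explicit offset sets, evaluated by a compiled min/max filter, so
grayscale and binary cases share one code path. The bottom-hat
(closing − image) highlights dark structures smaller than the element and
is the workhorse for isolating stained tubules from larger organelles.

**Gradient magnitude** is a central-difference estimate divided by the
per-axis voxel size, so anisotropic stacks get physically correct
boundary strength. It is the standard preprocessing for watershed on
objects without stained boundaries.

**Frangi vesselness** measures how tube-like the local Hessian eigenvalue
structure is, maximized over Gaussian scales (scale-normalized by
`sigma^2`). A tube of radius `r` responds most strongly near
`sigma = r/sqrt(2)`, which is how the scale list should be chosen.
Defaults `alpha = beta = 0.5` and `c` set to half the maximal Hessian norm
follow the classic formulation; polarity defaults to dark structures
(EM stains). Three modes exist: per-XY-slice 2-D, full 3-D (closed-form
eigenvalues of the 3x3 Hessian field), and *sequential-planes*: 2-D
vesselness computed in the XY plane and again in the ZX plane, combined by
voxel-wise maximum. The maximum was chosen as the combination rule because
it takes the union of tubular evidence — a tube invisible in one plane
(because it runs perpendicular to it) is caught in the other. Gaussian
smoothing is implemented as banded-matrix multiplication per axis, which
keeps whole-volume filtering inside BLAS. A small absolute structureness
floor zeroes the response where the Hessian norm is at floating-point
noise level, so constant images yield exactly zero.

**Region-of-interest restriction** rasterizes rectangles, ellipses or
polygons (even-odd rule) deterministically, runs the filter on a crop
padded by the filter support, and hard-replaces inside the ROI; outside
voxels are bit-identical to the input. Hard replacement (no feathering at
the ROI edge) was chosen for predictability: the interior eroded by the
filter support is provably identical to the global result, which is the
property the tests assert.

## Manual-tool equivalents

The brush rasterizes the stroke polyline with Bresenham lines and takes
the union of disks along it, so any inter-point spacing yields a gap-free
stroke. The superpixel brush selects every SLIC region the footprint
touches — always a superset of the plain footprint. The spot paints a
2-D disk; the 3-D ball interprets its radius in physical units and paints
the corresponding voxel-space ellipsoid, so on a 5x5x10 nm grid a 10 nm
ball has semi-axes of (2, 2, 1) voxels.

The magic wand takes the connected component of the seed within an
inclusive intensity window around the seed value; region growing instead
admits frontier voxels within `kappa` of the *evolving* region mean, with
a deterministic (linear-index-ordered) frontier. Default connectivity for
selection tools is 8 in 2-D and 26 in 3-D, with face-connectivity
available by flag.

The membrane click tracker turns tracing into shortest-path search: voxel
cost decreases with smoothed dark-ridge evidence, the search runs on the
8-connected pixel graph inside a corridor (default 40 px wide) around
each click chord, with edge weights `step_length * mean(end costs)`. Ties
are broken by an infinitesimal penalty proportional to the perpendicular
distance from the chord, so on a uniform-cost field the path is the
discrete straight segment, deterministically. The corridor width and cost
definition are this package's own choices; nothing canonical is claimed
for them. The 3-D line tracker (microtubule-style) interpolates anchors
linearly in *physical* coordinates and rasterizes one node per intersected
slice — on anisotropic grids this differs from naive voxel-space
interpolation, which is the point.

**Shape interpolation** between two key slices is classic morphological
interpolation: each slice's objects become signed distance fields
(positive inside, negative outside, exact Euclidean), and the intermediate
slice at integer position `z` is the zero superlevel set of
`(slice_b - z) * SDF_a + (z - slice_a) * SDF_b`. Using integer
slice-distance weights rather than a normalized fraction makes the blend
exactly symmetric in floating point, so interpolating a to b equals the
reverse bit-for-bit, and the endpoints are reproduced exactly. Multiple
objects are matched greedily by centroid proximity and blended pairwise;
unmatched objects are copied unchanged with a warning rather than faded
against an empty field, which would require an arbitrary vanishing rule.
**Line interpolation** resamples two open 1-px curves to equal arc-length
point counts, matches endpoints by proximity, blends point-wise and
re-rasterizes; branching curves are refused.

Thresholding is inclusive at both window bounds (a closed interval is the
least surprising reading) and intersects with the mask in masked scope.

## Semiautomatic engines

**SLIC.** Supervoxels are k-means-style clusters in (intensity, physical
position) space with distance
`D^2 = dI^2 + m^2 * d_phys^2 / S^2`, where `S` is the seed spacing and `m`
the compactness, defaulting to 5% of the dtype range. Physical coordinates
make supervoxels approximately isotropic on anisotropic grids. After the
iterations a connectivity enforcement pass relabels contiguous fragments
and merges fragments smaller than a quarter of the target size into an
adjacent region. The partition carries per-region intensity statistics and
the face-touching region adjacency; face adjacency (rather than including
corner contacts) was chosen because the subsequent graph-cut should only
pay for cuts through real shared surface.

**Graph-cut.** Regions become graph vertices; each adjacency gets
capacity `w_ij = exp(-|mean_i - mean_j| / sigma)`. The exponential mapping
turns the stated "difference between average intensities" into a
similarity: alike neighbours are expensive to separate, dissimilar ones
cheap. `sigma` defaults to 5% of the spread of region means. Seeded
regions obtain hard terminal links (capacity above the total finite edge
mass) to source or sink, and the segmentation is the min-cut side of a
max-flow computation (via igraph). On instances small enough to enumerate
every seeded 2-coloring, the returned cut attains the exhaustive minimum
(a property the test suite checks on 100 random graphs).

**Marker-controlled watershed** is priority-flood (Meyer's algorithm) from
the marker voxels over a relief: a compiled priority queue pops the
lowest-relief queued voxel, labels it from its queue entry, and queues
unlabeled neighbours at `max(relief, current level)`. Ties break by
insertion order, which is deterministic for deterministic input. The
relief is the image itself, its spacing-aware gradient magnitude
(`use_gradient = TRUE`, the right choice when boundaries are membranes or
otherwise locally contrasted), or any user-supplied boundary map. Voxels
with non-finite relief are never flooded, which is how the object
separation below restricts flooding to the foreground.

**Object separation** splits fused near-convex objects (clustered lipid
droplets being the canonical case): exact squared Euclidean distance
transform of the binary input — computed by per-axis parabola envelopes
with physical spacings, so anisotropy-aware by construction — then
h-maxima suppression at depth `min_depth` (default 2 physical units) via
grayscale reconstruction, regional maxima of the suppressed field as
markers, and priority-flood of the inverted distance inside the
foreground. Suppression depth trades over- against under-segmentation:
depth comparable to the voxel size removes maxima created by surface
noise, while genuine twin-lobe geometry survives. Regional maxima are
extracted with a reconstruction at an epsilon of 1e-3 (intensity units of
the distance field), far below any geometrically meaningful distance
difference and far above double-precision noise.

**Classifiers.** Two random-forest classifiers cover the two regimes:

* *Membrane detection* (per-voxel, per-2-D-slice, stacked for 3-D):
  features are Gaussian-smoothed intensity, gradient magnitude and both
  Hessian eigenvalues at each scale, differences of Gaussians between
  consecutive scales, and eight ring-context samples at a configurable
  radius, sorted to be approximately rotation invariant. The ring samples
  are a deliberate simplification of published ray/context feature sets —
  cheap, schema-documented, and sufficient for membrane-vs-lumen
  discrimination on the phantoms; they are not claimed to reproduce any
  published feature set exactly.
* *Supervoxel classification* (per-region): minimum, maximum, mean and the
  nine decile cuts through the region histogram, plus the mean of each
  feature over adjacent regions as neighbour context (falling back to the
  region's own features when it has no neighbours). Deciles were chosen as
  the "cuts through the histogram" because they are scale-free and fixed
  in number.

Training requires both classes with at least 10 samples each; the forest
seed, parameters and a feature schema id persist with the model, and
prediction refuses features computed under a different schema. The same
seed and data reproduce the forest exactly. Supervoxel predictions paint
the region probability into every member voxel, so the output is constant
within regions by construction.

## Quantification

Connected components (2-D per slice or 3-D, configurable connectivity)
are measured in physical units: voxel count, volume/area, centroid,
intensity minimum/maximum/mean, eccentricity and orientation from the
second-moment equivalent ellipse (with the 1/12 variance of a unit square
added per axis, the standard discrete correction), and 2-D perimeter by a
four-direction Cauchy–Crofton estimate,
`P = pi/8 * (c_0 + c_90 + (c_45 + c_135)/sqrt(2))`, whose weights are the
exact scan-line spacings — no fitted constants. These estimator choices
are this package's own; other reasonable estimators exist.

Property filtering removes objects outside conjunctions of ranges from
both table and label volume, is idempotent, and is the polishing stage
after threshold-style segmentation. Model smoothing applies per-material
binary opening; opening is anti-extensive, so materials can never bleed
into each other. Manual measurements (distance, angle, caliper as the
projection extent of the selection along the anchor direction,
least-squares circle radius) work in physical coordinates and attach an
intensity profile sampled by trilinear interpolation at half the minimum
voxel dimension. Tables export as CSV/TSV with unit-suffixed headers at
six significant digits.

## Pipelines and the 13-step mitotic-cell workflow

A `PipelineRecipe` is an ordered list of (op, parameters) over a
registered vocabulary, serializable to YAML, replayed deterministically
under its seed, with every executed step appending to the action log and a
per-step report (timings, selection/material counts). A failing step
halts with its index and cause, preserving partial state.

The built-in mitotic-cell recipe segments a densely packed metaphase cell
by peeling off organelle classes in order of how easily they can be
isolated, degrading the image after each stage so later stages see a
simpler scene: diffusion; bottom-hat to suppress everything larger than
the ER tubule scale; sequential XY/ZX vesselness thresholded into the ER
model (intersected with an ER-plausible intensity window — the vesselness
evidence alone cannot distinguish a stained tubule from the rim of a much
darker sphere); replacement of ER voxels by the median background level;
thresholding of the very dark singular organelles; 3-D erosion–dilation
smoothing with size-based assignment into peroxisome/lysosome/lipid-droplet
materials (the three classes are separable by volume on this specimen
type); their replacement; masked thresholding of the chromosome mass
inside a user-supplied central-area mask (chromosome and mitochondrial
contrasts are too close for global thresholding — the phantom reproduces
this, including dark chromatin mottling that a singular-organelle
threshold picks up); smoothing into the chromosome model; replacement plus
a second diffusion; grayscale opening and thresholding for mitochondria;
smoothing and small-object filtration into the mitochondrion model; and
final combination. All numeric step parameters are exposed recipe
parameters whose defaults were tuned on the package's own phantom and are
explicitly non-canonical. In testing, the central-area mask is derived
from the phantom's chromosome ground truth dilated by a small margin; in
real use it is hand-drawn (brush plus shape interpolation) — both paths go
through the same `aux` input.

The ER threshold workflow (global thresholding, 3-D labelling, minimum-
volume filtering, assignment to an "ER" material) covers the
high-contrast, cytochemically stained regime where quantification
filtering alone polishes the result.

## The synthetic phantoms

The fixtures module renders spheres, random-walk tubular networks, curved
membrane sheets, membrane-bounded nuclei, fused sphere pairs (with the
analytic bisector plane recorded for validating separation), and a
composite mitotic-cell phantom with six organelle classes whose mean
darkness ordering follows the stained-specimen situation described above.
Objects are rendered with one-voxel partial-volume antialiasing, then
Gaussian noise (default 5% of the 8-bit range) and optional slice-wise
linear intensity drift are added; ground truth is the pre-noise ideal
label field, and identical seeds reproduce phantoms bit-for-bit.

What the phantoms emulate: contrast orderings and contrast proximity
(chromosome vs mitochondria), partial-volume boundaries, additive noise,
slice-wise intensity drift, anisotropic voxel grids, fused-object
geometry, crowding of a tubular network around other organelles. What
they do not: structured/correlated detector noise, charging and curtaining
artifacts, membrane substructure, deformable or branching organelle
shapes, staining heterogeneity beyond the chromosome mottling. Passing
phantom tests therefore demonstrates algorithmic correctness and
parameter-recovery behavior under idealized contrast, not segmentation
accuracy on any real specimen; on real data every threshold in the
recipes is expected to need retuning, which is why all of them are
exposed parameters.

Problem sizes in the validation runs are chosen for desk-scale iteration
on a single CPU: oracle checks at up to 12 regions / 12x12 grids (100
random instances each), seeded-engine recovery at 64–96 voxels per side,
object separation at radius-10 spheres on isotropic and 5:1 anisotropic
grids, and the mitotic workflow at 128 per side in the test suite and the
generator default of 192 per side in the acceptance script. These sizes
are the package's own validation choices; the algorithms have no inherent
size coupling beyond memory and time.

## Numerical and determinism notes

* All segmentation engines are deterministic given their inputs and
  seeds; priority-flood ties break by insertion order, SLIC seeds on a
  fixed grid, forests are seeded.
* Binary blends and label operations avoid float division where exactness
  matters (integer-weight SDF blending; inclusive integer thresholds).
* The squared EDT is exact (Felzenszwalb–Huttenlocher), not chamfer;
  infinite-valued sites are skipped in the envelope construction.
* Grayscale reconstruction uses the raster/anti-raster + FIFO hybrid, so
  h-maxima cost is near-linear.
* Bounded histories evict oldest-first; undo/redo stacks are per scope.

## Known limitations

* No out-of-core or memory-mapped volumes; everything lives in RAM as
  doubles during processing.
* No joint 5-D (Z and Time together) segmentation; time frames are
  independent.
* Membrane-classifier context features are a simplification (see above).
* Translation-only stitching; no rotational or elastic alignment.
* No segmentation-accuracy metrics framework is included; validation here
  is phantom-based by design.
* The 13-step recipe's defaults are phantom-tuned and must be treated as
  starting points on real data.
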