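---
title: "MRI-CBCT fusion of the temporomandibular joint: models and methods"
author: "tmjfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MRI-CBCT fusion of the temporomandibular joint: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmjfuse)
```

## The problem

Temporomandibular joint (TMJ) diagnosis needs two complementary views of
the same anatomy: the fibro-cartilaginous articular disc is only visible
on MRI (as a dark biconcave structure between condyle and fossa), while
the osseous surfaces — condylar head, glenoid fossa, articular eminence —
are only sharply delineated on (cone-beam) CT.  `tmjfuse` implements the
workflow that joins them: rigid multimodal registration into one world
coordinate system, fusion, semi-automatic segmentation, unsmoothed 3-D
surface reconstruction, and quantification of how reproducibly one
observer can repeat the segmentation.

World coordinates are mm in LPS orientation (the DICOM patient frame);
voxel indices are 0-based with voxel centres at integer indices, and
`world = origin + direction %*% (index * spacing)`.

## Registration model

The CBCT volume is fixed; the MR volume moves under a similarity
transform with 6 free parameters (pitch/roll/yaw Euler angles applied
intrinsically about x, then y, then z, in degrees, plus a translation in
mm).  A 7th parameter, isotropic scale, exists in the model but is
frozen at 1 by default: the pose difference between two scans of one
patient is rigid, and freeing scale only adds a flat direction to the
search.  The rotation centre is the fixed volume's centre.

Because MR and CBCT grey values do not correspond linearly, similarity
is measured on the joint intensity histogram of the overlapping voxels:
64 equal-width bins per axis spanning each volume's observed range.
Out-of-bounds samples are *excluded* (not zero-filled), so partial
overlap does not inject a spurious background peak; the histogram is
renormalised over in-bounds pairs only.  From the joint probability
`p(x, y)`:

* mutual information `MI = H(X) + H(Y) - H(X, Y)` in bits
  (base-2 logarithms, `0 log 0 = 0`), and
* the overlap-invariant normalised form
  `NMI = (H(X) + H(Y)) / H(X, Y)`, ranging over (1, 2].

NMI is the default similarity because it is insensitive to how much of
the two volumes happens to overlap during the search; plain MI is
available (`similarity = "mi"`), and the choice is recorded in the
result.

### Optimisation

Powell's conjugate-direction method maximises the similarity without
derivatives: successive line maximisations (Brent's method, bracketing
by outward expansion from the current point so the search stays local)
along a direction set that is updated with the cycle's net displacement
under the standard replacement tests.  Registration runs in two stages:

| stage | grid | Powell tolerance | purpose |
|-------|------|------------------|---------|
| 1 | fixed grid subsampled 4x | 1e-2 | fast capture from the rough initialisation |
| 2 | full resolution | 1e-4 | sub-voxel refinement |

Initialisation aligns the intensity centroids of the two volumes
(translation only, no rotation).  Parameters are naturally scaled — one
unit is 1 mm or 1 degree, which move the image by comparable amounts at
TMJ field-of-view sizes — so a single line-search bracket serves all six.
Every objective evaluation is logged in the result's `trace`.

The registration is fully deterministic: no random restarts, no
stochastic sampling.  Reported similarity always equals the value
recomputed from the returned transform.

### Why the native MR grid

The MR acquisition is anisotropic: 3 mm slices with a 0.3 mm gap
(slice pitch 3.3 mm) against 0.25 mm isotropic CBCT.
`fillSliceGaps()` rebuilds a uniform fine grid by *replicating* the
nearest acquired slice into the gaps — the right operation for fusion
display, because it never invents intensities.  For registration,
however, replication makes the similarity piecewise-constant along the
slice axis (a translation smaller than the pitch changes almost no
sample), which destroys sub-voxel recovery.  `registerVolumes()`
therefore samples the *native* anisotropic MR volume with trilinear
interpolation, which is continuous in the transform parameters.  Gap
filling remains part of the fusion/visualisation path.

## Segmentation

* `thresholdSegment()` marks the closed HU interval [300, 1000] by
  default — the osseous window on CBCT.  Both ends are configurable
  because CBCT grey values are only approximately HU-calibrated and
  scanner-dependent.  No morphological cleanup is applied by default;
  the workflow this models corrects masks manually
  (`editMask(base, additions, erasures)`, erasure winning on conflict).
  An optional `largestComponent()` filter exists but is off.
* `applyCrop()` zeroes voxels whose *centres* fall outside an oriented
  box; the box's centre, extents and pitch/roll/yaw serialise to JSON
  bit-exactly so a later session crops identically.  The default extent
  is a 25 mm cube: read from "about 2.5 cm" per side, since a box of
  2.5 cm^3 volume (~13.6 mm sides) could not contain condyle, fossa and
  eminence together.
* `contoursToMask()` rasterises manually traced per-slice disc polygons
  by the even-odd rule on voxel centres; self-intersecting polygons are
  rejected per slice, vertex order is irrelevant, and multiple polygons
  on one slice combine by parity.

The voxel-centre inclusion rule (rather than any-overlap) is used for
both cropping and rasterisation; it is unbiased for closed regions and
makes counts exactly reproducible.

## Surface models

`maskToMesh()` extracts the iso-0.5 surface of the binary mask by
marching tetrahedra: each cell of 8 voxel centres is split into six
tetrahedra around a common diagonal, which induces matching face
diagonals in neighbouring cells, so the mesh is watertight and free of
the ambiguous configurations of cube-based case tables; iso-vertices sit
at edge midpoints.  The mask is padded by one background layer first so
structures touching the grid border still close.  **No smoothing,
decimation or hole filling is applied** — the point of the downstream
metrics is to measure the segmentation, not a beautified surface — so
repeated extractions are bit-identical.  STL export is the little-endian
binary dialect (80-byte header, uint32 count, 50-byte records); a JSON
sidecar records units (mm) and the structure label, which STL itself
cannot carry.  ASCII STL is read by sniffing.

## Reproducibility metrics

For two models of one structure, `compareModels()` reports:

* **RMSD / MD** — every vertex of model A is projected to its nearest
  point on any triangle of B (true point-to-triangle distance, not
  vertex-to-vertex), and symmetrically from B to A; RMSD is the root
  mean square and MD the maximum of the pooled distances.  "Perpendicular
  distance" is read as this nearest-surface distance (the perpendicular
  foot on the nearest triangle).  Symmetric pooling is the default
  because it bounds both omission and commission errors; a
  one-directional mode exists and is recorded in the report.  The
  accelerated uniform-grid search is verified against an exhaustive
  brute-force oracle to 1e-12.
* **DSI** — `2|A∩B| / (|A|+|B|)` on the reference voxel grid (meshes are
  voxelized by even-odd ray casting; masks are used directly); defined
  as 1 when both masks are empty.

`descriptiveStats()` gives the arithmetic mean and the *sample* standard
deviation (n-1 denominator, 0 for n = 1).  Reported values can be
rounded half-up or truncated; truncation is the default for table
reproduction because published clinical tables of this kind truncate
(their own software quantises values toward zero), and it is the only
mode consistent with every column of the worked example shipped in
`inst/extdata/tmj_reproducibility.csv`.

## The digital phantom

`generatePhantom()` renders a stylised closed-mouth TMJ with known
ground truth: an ellipsoidal condylar head (6.5 x 5 x 4.5 mm semi-axes,
mediolaterally widest as in life — the in-plane anisotropy also makes
all three rotations identifiable), a spherical-shell glenoid fossa dome
above it, a biconcave disc filling 70% of the condyle-fossa gap (so the
truth masks are disjoint by construction), and a bright retrodiscal
ellipsoid visible on MR only.  CT intensities: soft-tissue background
40 HU, bone 600-700 HU, so the 300-1000 HU window brackets bone with
margin.  MR intensities: soft tissue 120, bone 40, disc 30 (dark),
retrodiscal 200 (bright), in arbitrary units.

Two rendering choices matter for realism:

* **Partial volume.** Occupancy is supersampled 3x3x3 at boundary
  voxels, so structure edges are anti-aliased and thresholding sees
  realistic boundary blur; truth masks are the occupancy >= 0.5 voxels.
  MR voxels additionally average the anatomy across their full 3 mm
  slab.
* **Texture.** A smooth deterministic intensity field (7-11 mm periods)
  is added to both modalities, emulating the trabecular and soft-tissue
  inhomogeneity that carries alignment information away from structure
  boundaries in real scans.  Without it the phantom is piecewise
  constant and mutual information is driven by boundaries alone, which
  leaves the similarity maximum measurably biased (about a degree in
  yaw); with it the similarity peaks at the ground truth to well within
  the acceptance tolerances.

The MR volume is rendered in the frame displaced by the ground-truth
transform (default (4, -3, 2) mm, (3, -2, 5) degrees about the CT
centre), default grids 112 x 112 x 72 at 0.25 mm (CT) and 10 slices of
64 x 64 at 0.5 mm in-plane (MR).  Noise is additive Gaussian per
modality, default 0; the noisy registration condition uses MR noise at
5% of the soft-tissue/bone contrast (4 a.u.) and 10 HU on CT.  Gaussian
rather than Rician noise is a deliberate simplification; at these
signal-to-noise levels the difference is negligible for the metrics
tested.  All randomness derives from the `PhantomSpec` seed, and the global
RNG state is saved and restored, so identical specs give bit-identical
phantoms.

What the phantom does *not* emulate: metal and motion artifacts,
magic-angle signal changes, open-mouth positioning, intensity
inhomogeneity fields, or anatomical shape variation.  Passing tests on
the phantom therefore demonstrate correctness of the algorithms under
the stated acquisition geometry, not clinical performance on patient
images.

`perturbMask()` emulates intra-observer re-segmentation: the signed
Euclidean distance to the mask boundary (exact 3-D distance transform)
is thresholded against a smooth random field (iid normals on a ~2 mm
lattice, trilinearly upsampled, rescaled to RMS = magnitude).  Magnitude
0 reproduces the input exactly; the expected Dice decreases
monotonically with magnitude.

## Numerical choices and degenerate inputs

* Histogram bin edges span each image's observed range; with fewer than
  1% of fixed voxels overlapping, the histogram is refused with the
  overlap fraction in the message.
* Entropies use `0 log 0 = 0`; NMI refuses constant images (zero
  marginal entropy).
* Gap filling resolves exact midpoint ties to the lower slice index.
* Mesh voxelization casts rays at a ~1e-3-voxel diagonal offset from
  voxel centres so rays cannot hit mesh vertices or edges exactly.
* Empty masks cannot be meshed (error); an all-outside crop warns and
  returns an empty mask; DSI of two empty masks is 1 by convention.
* Powell refuses a non-finite objective at the start; line searches
  never accept a point worse than their origin.

## Problem sizes used in the tests

The shipped tests register the default-resolution phantom (0.9M CT
voxels) twice — noise-free and at the noisy condition — in roughly ten
seconds each; unit-level registration properties use a half-resolution
phantom.  Mesh and metric oracles run on digital balls up to 10 mm
radius (0.7M voxels).  These sizes were chosen so the whole suite
exercises every full-resolution code path while staying comfortable to
run locally.

## Known limitations

* Rigid/similarity registration only; no deformable model, so open-mouth
  sequences (different condyle-fossa relation) cannot be fused to a
  closed-mouth CBCT.
* The DICOM codec covers uncompressed explicit-VR little-endian
  single-frame series — sufficient for the geometry and pixel data of
  exported scanner series, but not compressed transfer syntaxes or
  private tags.  DICOM voxel values are stored as 16-bit integers, so
  round trips are exact only for integer-valued data (scanner data are).
* Disc segmentation is manual by design (contours in, mask out); no
  automatic disc detector is provided.
* Inter-observer statistics beyond mean/SD (e.g. ICC) are out of scope.
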