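---
title: "Classical brain tumor segmentation: methods and design notes"
author: "gliomaSeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classical brain tumor segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomaSeg)
```

# Scope

gliomaSeg implements two classical, fully automatic whole-tumor
segmentation pipelines for single-modality, skull-stripped,
bias-corrected 3D MRI (FLAIR, T2-w or T1-Gd) in NIfTI format, together
with the standard evaluation metrics (Dice similarity, boundary
Hausdorff distance, volume) and a synthetic phantom generator that
provides ground truth without any data download. A particular concern
throughout is *clinical-style* data: low-resolution 2D acquisitions
with thick slices and a non-zero inter-slice gap, as opposed to the
isotropic research-grade volumes most segmentation tools are built
around. Both pipelines are intrinsically 2D and process axial slices
individually, so non-contiguous slices are handled at native
resolution; no resampling is ever performed.

# Hemisphere-symmetry region growing

The region-growing pipeline rests on two anatomical assumptions: the
two brain hemispheres are approximately mirror symmetric, and the
tumor occupies one hemisphere only. Its stages are:

1. **Vertical alignment.** An exhaustive grid search over in-plane
   rotations (±20° in 0.5° steps) and candidate midline columns (the
   central third of the x range) maximises the Dice-style mirror
   overlap of the head mask with its reflection. The search is
   deterministic, with fixed tie-breaks (smaller |rotation|, then
   midline closer to the volume centre). Resampling is
   nearest-neighbour so intensities are never interpolated.
2. **Hemisphere split and mirrored subtraction.** The aligned volume
   is split at the midline column (the column itself excluded) and
   each hemisphere is subtracted voxel-wise from the mirror of the
   other. Supra-threshold voxels of the absolute difference form the
   tumor candidate region; the threshold is `asymmetryThreshold`
   (default 3) times a robust noise scale, 1.4826 × MAD of the signed
   difference. Only voxels that are in-brain *on both sides* enter the
   comparison: when the head centre falls between voxel columns (any
   even matrix), mirroring about a column mispairs the head rim by one
   voxel, and a union-based difference would be dominated by that
   artifactual band.
3. **Side attribution.** Each candidate voxel is attributed to the
   hemisphere that is brighter at that position (tumors are
   hyperintense on FLAIR/T2). The declared tumor side carries the
   larger summed supra-threshold mass; the confidence is its share of
   the total. An exactly mirrored bilateral tumor cancels in the
   subtraction, leaving no supra-threshold mass and a confidence of
   0.5 — indistinguishable, by symmetry alone, from a tumor-free
   brain. Any confidence below `bilateralConfidenceFloor` (default
   0.65) therefore flags the run *bilateral-suspect* rather than
   silently returning a wrong mask: this is the documented blind spot
   of the method, and the flag operationalises its unilaterality
   assumption.
4. **Per-slice stretch, seed, grow.** On each slice intersecting the
   candidate region, in-brain intensities are contrast-stretched
   linearly from the (1st, 99th) percentiles onto [0, 1]; the seed is
   the brightest candidate voxel (lexicographic tie-break); breadth
   growth collects all connected voxels (8-connectivity by default)
   within `intensityTolerance` (default 0.2, in stretched units) of
   the seed intensity, measured against the seed rather than a running
   mean — the simplest deterministic reading of "similar intensity
   levels". Enclosed in-plane holes of the grown region are then
   filled: the necrotic core is darker than the edema shell that
   encloses it, and the target of this pipeline is the *whole* tumor.
5. **Output.** Per-slice masks are unioned, mapped back through the
   inverse alignment rotation, and returned as label 2 with an
   `undifferentiated` flag — the method cannot tell edema from
   necrosis, which the evaluation module reports as "not produced"
   rather than zero.

Two places where noise handling required care. A mask-aware Gaussian
pre-smoothing (`smoothSigma`, default 1 voxel in-plane; normalised
convolution so the zero background neither bleeds in nor out) is
applied *only* for asymmetry detection and seed placement. Growth
itself runs on the unsmoothed stretched slice: smoothing would erode
the grown boundary by roughly a kernel width, while seeding from the
smoothed image means the seed intensity is a typical tumor value
rather than the brightest noise excursion — which would otherwise
shift the acceptance window `|I − I_seed| ≤ tol` off the tumor
intensity distribution. Second, candidate components smaller than
`minCandidateVoxels` (default 10) per slice are discarded before side
attribution, so isolated noise spikes cannot decide the tumor side of
a tumor-free brain.

# Fuzzy C-means clustering

The solver minimises the classical fuzzy within-cluster cost

$$J = \sum_{j=1}^{N}\sum_{i=1}^{C} w_{ij}^{m}\,\lVert x_j - c_i\rVert^2$$

over scalar voxel intensities \(x_j\), centroids \(c_i\) and
memberships \(w_{ij}\), alternating the centroid update
\(c_i = \sum_j w_{ij}^m x_j / \sum_j w_{ij}^m\) with the standard
membership update

$$w_{ij} = \Bigl[\sum_{k=1}^{C}
  \bigl(\lVert x_j - c_i\rVert / \lVert x_j - c_k\rVert\bigr)^{2/(m-1)}
  \Bigr]^{-1},$$

the stationarity condition of \(J\) under the sum-to-one constraint.
(A membership rule built from the *un*-reciprocated sum of squared
distance ratios, without the \(m\)-dependence, does not normalise the
rows and is not a descent direction for \(J\); only the standard
update gives the guaranteed monotone cost that the test suite
asserts.) A point coinciding with one or more centroids receives its
membership split equally among them. Iteration stops when the largest
centroid displacement falls below `tol` (default 1e-5 intensity units)
or after `maxIter` (200). Centroids are returned sorted ascending.

**Initialisation** is deterministic: C centroids evenly spaced over
the data range. Quantile-based starts fail on brain images, where the
normal-brain mode holds well over three quarters of the voxels: most
quantile centroids then coincide inside that mode, receive identical
memberships forever, and the minority tumor tissues never acquire a
centroid. Range spacing is scale-equivariant and separates minority
modes; a seeded random start over distinct data values is available
(`init = "random"`) for restart experiments.

**Cluster-to-tissue mapping.** The defaults use C = 4 (a
background-like class, normal brain, necrotic core, edema on
FLAIR-like contrast). Mass-weighted clustering happily spends two
clusters halving the heavy brain mode — or occasionally the edema mode
— so cluster index alone does not identify tissue. Adjacent clusters
whose centroid gap sits at the noise level (below `minSeparation` = 4
times the MAD of the bottom cluster's values) are therefore merged
into *tissue groups*. The top group is edema (label 2); the highest
cluster of the group below it is relabelled necrotic (label 1) where
its voxels fall inside the filled convex hull of the slice's edema —
necrosis is by definition interior to the tumor, and intensity alone
cannot distinguish it from dark normal structures elsewhere. If all
clusters collapse into a single group, nothing on the slice stands
clear of the noise and the slice is left unlabelled: without this
tumor-presence test the brightest quarter of the noise distribution
masquerades as edema on every tumor-free slice. Finally each label is
cleaned by area opening (`minArea`, default 20 voxels in-plane,
8-connectivity), with the necrotic territory bounded by the hull of
the *cleaned* edema.

Known behaviour worth stating plainly: a tissue represented by a
single voxel on a slice (an ellipsoid tip falling exactly on a slice
centre) cannot hold a centroid against tens of thousands of brain
voxels — this is fundamental to mass-weighted clustering, not an
implementation limit. The phantom suite therefore places tumor
extents so ellipsoid tips fall between slice centres. Under a strong
multiplicative bias field the clustering degrades markedly (the
`noisy_biased` fixture shows this), which is precisely the documented
weakness of conventional FCM under intensity inhomogeneity; no
bias-corrected FCM variant is implemented.

# Evaluation metrics

* **Dice**: \(2|A\cap B|/(|A|+|B|)\); by stated convention 1.0 when
  both masks are empty and 0.0 when exactly one is.
* **Hausdorff**: the plain (100th-percentile) symmetric max-min
  Euclidean distance between *boundary voxels* — foreground voxels
  with a background or out-of-volume face neighbour (6-connectivity
  in 3D), the strictest common boundary definition. Distances are in
  voxel units by default; in mm the through-slice step is
  `dz + sliceGap`, the centre-to-centre distance of non-contiguous
  slices. A Hausdorff against an empty mask is *undefined* and
  reported as such (flagged, excluded from batch means with an
  exclusion count), never coerced to a number. The implementation is
  checked exactly against a brute-force all-pairs oracle on random
  masks.
* **Volume**: the voxel count, and count × dx × dy × dz in mm³. The
  slice gap is never folded into mm³ — tissue in the gap was simply
  not imaged — and its presence is reported as a caveat flag instead.

Components are evaluated as whole tumor (labels ≥ 1), edema (2) and
necrotic (1); an undifferentiated prediction yields "not produced"
entries for the components, mirroring the dash convention of
method-comparison tables.

# The phantom generator

`makePhantom()` emulates exactly the features the algorithms and
metrics exercise: an ellipsoidal head of symmetric hemispheres at
constant brain intensity; a tumor built of concentric ellipsoids
(necrotic core inside an edema shell) with FLAIR-like ordering
background < brain < necrotic < edema (defaults 0/120/160/200);
additive Gaussian noise inside the brain only (background stays
exactly zero, as skull stripping leaves it; default fixtures use
σ = 8, i.e. an edema–brain contrast-to-noise of 10, a realistic FLAIR
regime); an optional smooth multiplicative bias field (product of
per-axis quadratics, amplitude-normalised over the head); and an
optional in-plane rotation. Right-sided and bilateral phantoms are
exact array mirrors of the left-sided construction, so mirror
properties hold bit-exactly. Gaussian rather than Rician noise is
used: at these signal-to-noise ratios the distinction is second-order
for magnitude images, and none of the algorithms under test is
sensitive to it. The clinical preset uses a 256 × 224 in-plane matrix
at 0.5 mm (scaled down from a full clinical matrix for speed), 20
slices of 5 mm with a 1.5 mm gap (6.5 mm centre-to-centre); an
isotropic 1 mm geometry is available by override.

What the phantom deliberately does **not** emulate: cortical folding
and tissue texture, partial-volume ramps at tissue interfaces,
acquisition physics, or irregular tumor shapes. Passing on the
phantom therefore demonstrates correctness of the implementations and
their stated invariants — not clinical-grade accuracy: on the
piecewise-constant phantom both pipelines score far above anything
attainable on real data, where tissue boundaries are graded, shapes
irregular and intensities inhomogeneous.

# Numerical choices and degenerate inputs

* Thresholds derived from robust scale estimates are floored at 1e-6
  of the intensity scale: on a noise-free volume the MAD is exactly 0
  and a strict "> 0" test would otherwise trip on the ~1e-13 rounding
  residue of resampling and normalised-convolution arithmetic.
* Contrast stretching treats a percentile spread at rounding level as
  a constant slice (all zeros, with a warning); growth is skipped on
  slices whose seed stretches to 0 — growing from a zero seed would
  flood the background.
* All tie-breaks are fixed and documented: seed selection takes the
  smallest (row, col); alignment prefers smaller |rotation| then the
  more central midline; membership ties in hard assignment go to the
  higher centroid.
* Degenerate FCM input (all values identical) returns one centroid at
  that value with the remaining clusters flagged empty and
  `converged = FALSE`, rather than erroring mid-volume.
* Mirroring is pure array reversal and rotation is nearest-neighbour:
  no interpolation anywhere, so symmetry tests can assert exactness.

# Problem sizes

The test suite and the acceptance script validate on the clinical
preset (256 × 224 × 20, ~317k brain voxels per phantom) for the
pipeline-level checks, on ~60 × 55 × 12 phantoms for per-module tests,
and on ≤ 8³ masks for the brute-force oracle comparisons; these sizes
keep a full run within a few minutes while leaving every tissue with
thousands of voxels on the slices that matter.

# Limitations

Single modality only, 2D slice-wise processing, no spatial
regularisation in the clustering, no bias-field correction, no
registration or resampling, and the bilateral blind spot described
above: mirrored bilateral disease is *flagged*, not segmented. The
evaluation module reports what the region-growing method cannot
produce instead of imputing it. These are properties of the classical
methods themselves, reproduced deliberately.
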