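## Condition helper used everywhere user input is validated; the CLI maps
## this class to exit code 2.
stopValidation <- function(msg, ...) {
  stop(structure(class = c("segValidationError", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' BrainVolume: a 3D scalar MRI volume with acquisition geometry
#'
#' Container for a single-modality, skull-stripped 3D image. Voxel axes
#' follow a fixed anatomical convention after loading: x = left to right,
#' y = posterior to anterior, z = inferior to superior (RAS). Background
#' (non-brain) voxels are expected to be exactly zero, as produced by
#' brain extraction.
#'
#' @slot data 3D numeric array of intensities (arbitrary MRI units).
#' @slot spacing numeric(3), voxel size (dx, dy, dz) in mm; dz is the
#'   acquired slice thickness.
#' @slot sliceGap mm between the edges of consecutive acquired slices
#'   beyond \code{dz} (0 for contiguous acquisitions); center-to-center
#'   slice spacing is \code{dz + sliceGap}.
#' @slot affine 4x4 voxel-to-world transform (after reorientation).
#'
#' @export
setClass("BrainVolume",
  representation(data = "array", spacing = "numeric", sliceGap = "numeric",
                 affine = "matrix"),
  prototype(sliceGap = 0, affine = diag(4)))

setValidity("BrainVolume", function(object) {
  msgs <- character(0)
  d <- dim(object@data)
  if (length(d) != 3L || any(d < 1L))
    msgs <- c(msgs, "data must be a 3D array with positive dimensions")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be three positive finite values (mm)")
  if (length(object@sliceGap) != 1L || !is.finite(object@sliceGap) ||
      object@sliceGap < 0)
    msgs <- c(msgs, "sliceGap must be a single non-negative value (mm)")
  n_nan <- sum(is.nan(object@data))
  if (n_nan > 0)
    msgs <- c(msgs, sprintf("data contains %d NaN voxel(s)", n_nan))
  if (!all(dim(object@affine) == c(4L, 4L)))
    msgs <- c(msgs, "affine must be a 4x4 matrix")
  if (length(msgs)) msgs else TRUE
})

#' TumorMask: integer tumor label volume
#'
#' Label volume sharing a \linkS4class{BrainVolume}'s geometry. Label
#' encoding: 0 = background, 1 = necrotic core, 2 = edema; the whole
#' tumor is the union (labels >= 1). Masks produced by the region-growing
#' pipeline carry \code{undifferentiated = TRUE}: the whole tumor is
#' stored as label 2 and the components are not individually resolved.
#'
#' @slot labels 3D integer array with values in \{0, 1, 2\}.
#' @slot spacing,sliceGap geometry, as in \linkS4class{BrainVolume}.
#' @slot undifferentiated logical; TRUE when the mask encodes only the
#'   whole tumor (no edema/necrotic distinction).
#'
#' @export
setClass("TumorMask",
  representation(labels = "array", spacing = "numeric", sliceGap = "numeric",
                 undifferentiated = "logical"),
  prototype(sliceGap = 0, undifferentiated = FALSE))

setValidity("TumorMask", function(object) {
  msgs <- character(0)
  d <- dim(object@labels)
  if (length(d) != 3L || any(d < 1L))
    msgs <- c(msgs, "labels must be a 3D array with positive dimensions")
  if (!is.integer(object@labels))
    msgs <- c(msgs, "labels must be stored as integers")
  bad <- setdiff(unique(as.vector(object@labels)), c(0L, 1L, 2L))
  if (length(bad))
    msgs <- c(msgs, sprintf("unknown label value(s): %s",
                            paste(sort(bad), collapse = ", ")))
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be three positive values (mm)")
  if (length(object@sliceGap) != 1L || object@sliceGap < 0)
    msgs <- c(msgs, "sliceGap must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Parameters of the symmetry-based region-growing pipeline
#'
#' @slot intensityTolerance maximum absolute difference, in contrast-
#'   stretched units (the stretched slice lives in [0,1]), between a
#'   voxel and the seed for the voxel to join the grown region.
#' @slot connectivity in-plane pixel connectivity, 4 or 8.
#' @slot stretchPercentiles numeric(2), (low, high) percentiles of the
#'   in-brain intensities mapped to 0 and 1 by contrast stretching.
#' @slot asymmetryThreshold multiple of the robust (MAD-based) noise
#'   scale of the hemisphere difference image above which a voxel is a
#'   tumor candidate.
#' @slot bilateralConfidenceFloor minimum side-attribution confidence;
#'   below it the run is flagged "bilateral-suspect".
#' @slot smoothSigma std dev (voxels) of the in-plane Gaussian
#'   pre-smoothing applied inside the brain mask; 0 disables.
#' @slot minCandidateVoxels in-plane candidate components smaller than
#'   this are discarded before side attribution.
#'
#' @export
setClass("RGParams",
  representation(intensityTolerance = "numeric", connectivity = "integer",
                 stretchPercentiles = "numeric",
                 asymmetryThreshold = "numeric",
                 bilateralConfidenceFloor = "numeric",
                 smoothSigma = "numeric", minCandidateVoxels = "integer"))

setValidity("RGParams", function(object) {
  msgs <- character(0)
  if (object@intensityTolerance <= 0 || object@intensityTolerance >= 1)
    msgs <- c(msgs, "intensityTolerance must lie in (0, 1)")
  if (!object@connectivity %in% c(4L, 8L))
    msgs <- c(msgs, "connectivity must be 4 or 8")
  p <- object@stretchPercentiles
  if (length(p) != 2L || p[1] >= p[2] || p[1] < 0 || p[2] > 100)
    msgs <- c(msgs, "stretchPercentiles must be (low, high) in [0,100], low < high")
  if (object@asymmetryThreshold <= 0)
    msgs <- c(msgs, "asymmetryThreshold must be > 0")
  if (object@bilateralConfidenceFloor <= 0 || object@bilateralConfidenceFloor > 1)
    msgs <- c(msgs, "bilateralConfidenceFloor must lie in (0, 1]")
  if (object@smoothSigma < 0)
    msgs <- c(msgs, "smoothSigma must be >= 0")
  if (object@minCandidateVoxels < 0)
    msgs <- c(msgs, "minCandidateVoxels must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Parameters of the fuzzy C-means pipeline
#'
#' @slot nClusters number of clusters C (>= 2 for segmentation; the bare
#'   clustering routine accepts C = 1).
#' @slot m fuzziness exponent, > 1; m -> 1 approaches hard k-means.
#' @slot tol convergence threshold on the largest centroid displacement
#'   (intensity units).
#' @slot maxIter iteration cap.
#' @slot seed RNG seed, used only by the optional random initialisation.
#' @slot init "range" (deterministic, evenly spaced over the data range)
#'   or "random" (C distinct data points sampled with \code{seed}).
#' @slot minArea minimum in-plane connected-component area (voxels) kept
#'   by small-object cleanup.
#' @slot connectivity in-plane connectivity for the cleanup, 4 or 8.
#' @slot minSeparation tumor-presence test: the top (edema) cluster is
#'   accepted only when its centroid separation from the next cluster
#'   exceeds this multiple of the robust within-tissue noise scale;
#'   on a tumor-free slice the clusters merely band the noise and the
#'   separation stays at the noise level.
#'
#' @export
setClass("FCMParams",
  representation(nClusters = "integer", m = "numeric", tol = "numeric",
                 maxIter = "integer", seed = "integer", init = "character",
                 minArea = "integer", connectivity = "integer",
                 minSeparation = "numeric"))

setValidity("FCMParams", function(object) {
  msgs <- character(0)
  if (object@nClusters < 1L) msgs <- c(msgs, "C must be >= 1")
  if (object@m <= 1) msgs <- c(msgs, "m must be > 1")
  if (object@tol <= 0) msgs <- c(msgs, "tol must be > 0")
  if (object@maxIter < 1L) msgs <- c(msgs, "maxIter must be >= 1")
  if (!object@init %in% c("range", "random"))
    msgs <- c(msgs, "init must be 'range' or 'random'")
  if (object@minArea < 0L) msgs <- c(msgs, "minArea must be >= 0")
  if (!object@connectivity %in% c(4L, 8L))
    msgs <- c(msgs, "connectivity must be 4 or 8")
  if (object@minSeparation < 0) msgs <- c(msgs, "minSeparation must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Result of a fuzzy C-means fit
#'
#' @slot centroids numeric(C), sorted ascending; NA for clusters flagged
#'   empty by a degenerate fit.
#' @slot memberships N x C matrix; row j holds the memberships of data
#'   point j, each row sums to 1.
#' @slot cost final value of the fuzzy within-cluster cost
#'   J = sum_j sum_i w_ij^m (x_j - c_i)^2.
#' @slot costTrace J after every iteration (non-increasing).
#' @slot nIter iterations run.
#' @slot converged TRUE when the centroid-change criterion was met.
#' @slot empty logical(C), TRUE for clusters with no support.
#'
#' @export
setClass("FCMFit",
  representation(centroids = "numeric", memberships = "matrix",
                 cost = "numeric", costTrace = "numeric", nIter = "integer",
                 converged = "logical", empty = "logical"))

#' Result of hemisphere alignment
#'
#' @slot rotationDeg in-plane rotation (degrees, about the z axis)
#'   applied to align the interhemispheric plane with a voxel column.
#' @slot midlineX 1-based voxel column index of the interhemispheric
#'   plane in the aligned volume.
#' @slot aligned the rotated \linkS4class{BrainVolume}.
#'
#' @export
setClass("AlignmentResult",
  representation(rotationDeg = "numeric", midlineX = "integer",
                 aligned = "BrainVolume"))

setValidity("AlignmentResult", function(object) {
  msgs <- character(0)
  if (abs(object@rotationDeg) > 45)
    msgs <- c(msgs, "|rotationDeg| must be <= 45")
  nx <- dim(object@aligned@data)[1]
  if (object@midlineX < 2L || object@midlineX > nx - 1L)
    msgs <- c(msgs, "midlineX must be strictly inside the x extent")
  if (length(msgs)) msgs else TRUE
})

#' Result of mirrored hemisphere subtraction
#'
#' Both hemispheres are width-equalised (zero-padded at the lateral edge)
#' so that mirroring about the midline aligns them; the difference
#' volumes are stored in that padded hemisphere frame.
#'
#' @slot diffLeft,diffRight non-negative absolute difference volumes
#'   |hemisphere - mirrored other hemisphere| (numerically identical;
#'   both kept so side attribution stays explicit).
#' @slot tumorSide "left" or "right": side holding the larger summed
#'   supra-threshold asymmetry mass.
#' @slot candidateRegion logical array (padded hemisphere frame, own-side
#'   coordinates of \code{tumorSide}) of supra-threshold voxels.
#' @slot confidence fraction of the supra-threshold asymmetry mass on the
#'   declared side; 0.5 when there is no supra-threshold mass at all.
#' @slot threshold,noiseScale the applied threshold and the MAD-based
#'   noise scale it was derived from.
#'
#' @export
setClass("AsymmetryResult",
  representation(diffLeft = "array", diffRight = "array",
                 tumorSide = "character", candidateRegion = "array",
                 confidence = "numeric", threshold = "numeric",
                 noiseScale = "numeric"))

#' Result of the region-growing segmentation pipeline
#'
#' @slot mask whole-tumor \linkS4class{TumorMask} (label 2, flagged
#'   undifferentiated: the pipeline cannot resolve components).
#' @slot tumorSide,confidence side attribution diagnostics.
#' @slot bilateralSuspect TRUE when confidence fell below the configured
#'   floor: the unilaterality assumption of the method is suspect.
#' @slot rotationDeg,midlineX alignment diagnostics.
#' @slot slicesProcessed z indices on which growth ran.
#'
#' @export
setClass("RGSegmentation",
  representation(mask = "TumorMask", tumorSide = "character",
                 confidence = "numeric", bilateralSuspect = "logical",
                 rotationDeg = "numeric", midlineX = "integer",
                 slicesProcessed = "integer"))

#' Specification of a synthetic brain phantom
#'
#' Describes an ellipsoidal "head" of brain-intensity tissue containing a
#' two-compartment tumor (necrotic core ellipsoid inside an edema
#' ellipsoid), with optional in-plane rotation, smooth multiplicative
#' bias field, and additive Gaussian noise inside the brain. Background
#' stays exactly zero, as in skull-stripped data.
#'
#' @slot shape integer(3) volume dimensions (nx, ny, nz).
#' @slot spacing mm voxel size; \code{sliceGap} mm gap between slices.
#' @slot headSemiAxes ellipsoid semi-axes in voxels (x, y, z).
#' @slot tissueIntensities named numeric: background, brain, necrotic,
#'   edema mean intensities (must be strictly increasing in that order).
#' @slot noiseSigma additive Gaussian noise std (intensity units).
#' @slot biasAmplitude peak fractional deviation of the multiplicative
#'   bias field (0 disables).
#' @slot tumorCenter voxel coordinates (x, y, z) of the tumor center for
#'   the canonical left-hemisphere construction.
#' @slot coreRadius,edemaRadius in-plane tumor radii in voxels
#'   (edema > core > 0); the through-slice semi-axis is derived from the
#'   physical radius and the effective slice spacing.
#' @slot laterality "left", "right", "bilateral_mirrored", "midline" or
#'   "none" (tumor-free).
#' @slot rotationDeg in-plane rotation applied to the finished phantom.
#' @slot seed RNG seed (noise); the construction is deterministic.
#'
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric", sliceGap = "numeric",
                 headSemiAxes = "numeric", tissueIntensities = "numeric",
                 noiseSigma = "numeric", biasAmplitude = "numeric",
                 tumorCenter = "numeric", coreRadius = "numeric",
                 edemaRadius = "numeric", laterality = "character",
                 rotationDeg = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msgs <- character(0)
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msgs <- c(msgs, "shape must be three positive integers")
  if (any(object@spacing <= 0) || object@sliceGap < 0)
    msgs <- c(msgs, "spacing must be positive and sliceGap non-negative")
  ti <- object@tissueIntensities
  need <- c("background", "brain", "necrotic", "edema")
  if (!all(need %in% names(ti)))
    msgs <- c(msgs, "tissueIntensities needs background, brain, necrotic, edema")
  else if (!all(diff(ti[need]) > 0))
    msgs <- c(msgs, "tissue intensities must satisfy background < brain < necrotic < edema")
  if (!object@laterality %in% c("left", "right", "bilateral_mirrored",
                                "midline", "none"))
    msgs <- c(msgs, "unknown laterality")
  if (object@laterality != "none" &&
      !(object@edemaRadius > object@coreRadius && object@coreRadius > 0))
    msgs <- c(msgs, "must satisfy edemaRadius > coreRadius > 0")
  if (object@noiseSigma < 0) msgs <- c(msgs, "noiseSigma must be >= 0")
  if (object@biasAmplitude < 0 || object@biasAmplitude >= 1)
    msgs <- c(msgs, "biasAmplitude must lie in [0, 1)")
  if (length(msgs)) msgs else TRUE
})
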