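## Symmetry-based seeded region growing: per-slice contrast stretching,
## seed selection and connected growth on the tumor-bearing side.

#' Region-growing parameters
#'
#' All defaults are overridable; see \linkS4class{RGParams} for the
#' meaning and units of each field.
#'
#' @param intensityTolerance growth tolerance in stretched units (0,1).
#' @param connectivity in-plane connectivity, 4 or 8.
#' @param stretchPercentiles (low, high) stretch percentiles.
#' @param asymmetryThreshold candidate threshold in MAD multiples.
#' @param bilateralConfidenceFloor bilateral-suspect confidence floor.
#' @param smoothSigma in-plane Gaussian pre-smoothing sigma (voxels).
#' @param minCandidateVoxels minimum in-plane candidate component size.
#' @return An \linkS4class{RGParams}.
#' @export
rgParams <- function(intensityTolerance = 0.2, connectivity = 8,
                     stretchPercentiles = c(1, 99), asymmetryThreshold = 3,
                     bilateralConfidenceFloor = 0.65, smoothSigma = 1,
                     minCandidateVoxels = 10) {
  new("RGParams", intensityTolerance = intensityTolerance,
      connectivity = as.integer(connectivity),
      stretchPercentiles = as.numeric(stretchPercentiles),
      asymmetryThreshold = asymmetryThreshold,
      bilateralConfidenceFloor = bilateralConfidenceFloor,
      smoothSigma = smoothSigma,
      minCandidateVoxels = as.integer(minCandidateVoxels))
}

#' Contrast-stretch a 2D slice
#'
#' Linear rescale mapping the low stretch percentile of the in-brain
#' (non-zero) intensities to 0 and the high percentile to 1, clipping
#' outside [0, 1]. Enhances the bright tumor and suppresses surrounding
#' tissue ahead of seeded growth. The map is monotone non-decreasing.
#' A constant slice cannot be stretched and is returned as all zeros
#' with a warning.
#'
#' @param sliceImg numeric matrix; background must be 0.
#' @param params an \linkS4class{RGParams}.
#' @return matrix with in-brain values in [0, 1], background 0.
#' @export
contrastStretch <- function(sliceImg, params = rgParams()) {
  inb <- sliceImg != 0
  zero <- matrix(0, nrow(sliceImg), ncol(sliceImg))
  if (!any(inb)) {
    warning("empty slice: nothing to stretch")
    return(zero)
  }
  q <- stats::quantile(sliceImg[inb], params@stretchPercentiles / 100,
                       names = FALSE)
  # relative epsilon: a numerically constant slice (percentile spread at
  # floating-point rounding level) has no usable dynamic range either
  if (q[2] - q[1] <= 1e-8 * max(abs(q), 1)) {
    warning("constant slice: contrast stretch undefined, returning zeros")
    return(zero)
  }
  out <- (sliceImg - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out[!inb] <- 0
  out
}

#' Select the growth seed on a slice
#'
#' The voxel of maximum (stretched) intensity inside the candidate
#' region; ties are broken to the smallest (row, col) in lexicographic
#' order so the choice is deterministic.
#'
#' @param sliceImg numeric matrix (typically contrast-stretched).
#' @param candidateSlice logical matrix of candidate voxels.
#' @return integer c(row, col), or NULL when the candidate region is
#'   empty on this slice (the slice is skipped, not an error).
#' @export
selectSeed <- function(sliceImg, candidateSlice) {
  if (!any(candidateSlice)) return(NULL)
  v <- sliceImg
  v[!candidateSlice] <- -Inf
  hits <- which(v == max(v), arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  as.integer(hits[1, ])
}

#' Grow a connected region of similar intensity from a seed
#'
#' Collects every voxel connected to the seed (4- or 8-connectivity)
#' whose intensity lies within \code{intensityTolerance} of the seed
#' intensity. Equivalent to flood fill over the thresholded image, so
#' the result is by construction a single connected component
#' containing the seed.
#'
#' @param sliceImg numeric matrix with stretched intensities in [0, 1].
#' @param seed integer c(row, col) inside the image.
#' @param params an \linkS4class{RGParams}.
#' @return logical matrix: the grown region.
#' @examples
#' img <- matrix(0.1, 9, 9); img[3:7, 3:7] <- 0.9
#' sum(regionGrow(img, c(5, 5), rgParams(intensityTolerance = 0.2)))
#' @export
regionGrow <- function(sliceImg, seed, params = rgParams()) {
  nx <- nrow(sliceImg); ny <- ncol(sliceImg)
  if (length(seed) != 2L || seed[1] < 1L || seed[1] > nx ||
      seed[2] < 1L || seed[2] > ny)
    stopValidation("seed (%s) lies outside the %d x %d image",
                   paste(seed, collapse = ", "), nx, ny)
  s <- sliceImg[seed[1], seed[2]]
  th <- abs(sliceImg - s) <= params@intensityTolerance
  lab <- labelComponents2D(th, params@connectivity)
  lab == lab[seed[1], seed[2]]
}

#' Whole-tumor segmentation by hemisphere symmetry and region growing
#'
#' Full pipeline: vertical alignment, optional mask-aware Gaussian
#' pre-smoothing (used only to detect asymmetry and place the seed;
#' growth itself runs on the unsmoothed stretched slice so boundaries
#' stay sharp), hemisphere split, mirrored subtraction to locate the
#' tumor-bearing side, then per slice intersecting the candidate region:
#' contrast stretching, seed selection inside the candidate region,
#' connected growth, and filling of enclosed in-plane holes (the darker
#' necrotic core enclosed by the grown edema shell belongs to the whole
#' tumor). Per-slice masks are unioned, mapped back through the inverse
#' alignment rotation, and returned as a whole-tumor-only mask (label 2,
#' flagged undifferentiated: the method cannot resolve edema from
#' necrosis). The pipeline assumes a unilateral tumor; when the side-
#' attribution confidence falls below \code{bilateralConfidenceFloor}
#' the result is flagged bilateral-suspect, since an exactly mirrored
#' bilateral tumor cancels in the subtraction and defeats the method.
#'
#' @param vol single-modality, brain-extracted
#'   \linkS4class{BrainVolume}.
#' @param params an \linkS4class{RGParams}.
#' @return An \linkS4class{RGSegmentation}.
#' @examples
#' p <- makePhantom(phantomSpec(shape = c(41L, 35L, 9L), spacing = c(1, 1, 4),
#'                              headSemiAxes = c(16, 13, 3.5),
#'                              tumorCenter = c(13, 18, 5),
#'                              coreRadius = 2, edemaRadius = 5))
#' seg <- segmentRG(p$volume)
#' diceCoefficient(wholeTumor(tumorMaskOf(seg)), wholeTumor(p$mask))
#' @export
segmentRG <- function(vol, params = rgParams()) {
  stopifnot(is(vol, "BrainVolume"))
  al <- alignVertical(vol)
  dat <- al@aligned@data
  dims <- dim(dat)

  if (params@smoothSigma > 0)
    for (z in seq_len(dims[3]))
      dat[, , z] <- gaussianBlur2D(dat[, , z], params@smoothSigma)
  smooth <- brainVolume(dat, spacing = vol@spacing, sliceGap = vol@sliceGap)
  smoothAl <- new("AlignmentResult", rotationDeg = 0,
                  midlineX = al@midlineX, aligned = smooth)

  hemis <- splitHemispheres(smoothAl)
  asym <- asymmetryMap(hemis$left, hemis$right, params)

  # map the candidate region from the padded hemisphere frame back into
  # aligned-volume columns
  mid <- al@midlineX
  w <- dim(asym@candidateRegion)[1]
  cand <- array(FALSE, dims)
  if (asym@tumorSide == "left") {
    # padded row r corresponds to column mid - w + (r - 1)
    cols <- (mid - w):(mid - 1L)
    keep <- cols >= 1L
    cand[cols[keep], , ] <- asym@candidateRegion[which(keep), , ]
  } else {
    cols <- (mid + 1L):(mid + w)
    keep <- cols <= dims[1]
    cand[cols[keep], , ] <- asym@candidateRegion[which(keep), , ]
  }

  bilateral <- asym@confidence < params@bilateralConfidenceFloor
  if (bilateral)
    warning(sprintf(
      "bilateral-suspect: asymmetry confidence %.3f is below the floor %.2f; ",
      asym@confidence, params@bilateralConfidenceFloor),
      "the unilateral-tumor assumption of this method may be violated",
      call. = FALSE)

  # the smoothed volume drives detection (asymmetry, seed placement);
  # growth runs on the raw stretched slice so boundaries stay sharp and
  # the seed value is a typical tumor intensity, not a noise extreme
  raw <- al@aligned@data
  mask <- array(FALSE, dims)
  grown <- integer(0)
  for (z in seq_len(dims[3])) {
    cs <- cand[, , z]
    if (!any(cs)) next
    stretchedSm <- contrastStretch(dat[, , z], params)
    seed <- selectSeed(stretchedSm, cs)
    if (is.null(seed) || stretchedSm[seed[1], seed[2]] <= 0) next
    stretchedRaw <- contrastStretch(raw[, , z], params)
    # a slice whose raw percentile spread is degenerate stretches to all
    # zeros; growing from a zero-valued seed would flood it
    if (stretchedRaw[seed[1], seed[2]] <= 0) next
    g <- regionGrow(stretchedRaw, seed, params)
    g <- fillHoles2D(g, params@connectivity)
    mask[, , z] <- g
    grown <- c(grown, z)
  }
  if (!length(grown))
    warning("no slice produced a grown region: returning an empty mask",
            call. = FALSE)

  if (al@rotationDeg != 0) {
    m <- array(0L, dims)
    m[mask] <- 1L
    m <- rotateSlices(m, -al@rotationDeg)
    mask <- m == 1L
  }
  labels <- array(0L, dims)
  labels[mask] <- 2L
  new("RGSegmentation",
      mask = tumorMask(labels, spacing = vol@spacing,
                       sliceGap = vol@sliceGap, undifferentiated = TRUE),
      tumorSide = asym@tumorSide, confidence = asym@confidence,
      bilateralSuspect = bilateral, rotationDeg = al@rotationDeg,
      midlineX = al@midlineX, slicesProcessed = grown)
}
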