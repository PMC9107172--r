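## Mirrored hemisphere subtraction: locating the tumor-bearing side.

#' Mirrored hemisphere subtraction and tumor-side attribution
#'
#' Pads the narrower hemisphere with zeros at its lateral edge so both
#' have equal width when aligned at the midline, then forms the absolute
#' difference between each hemisphere and the mirror of the other.
#' Voxels whose difference exceeds \code{asymmetryThreshold} times the
#' robust noise scale (1.4826 x MAD of the signed difference over
#' voxels that are in-brain on both sides) are tumor candidates,
#' attributed to the brighter side (tumors are hyperintense on
#' FLAIR/T2). Tiny in-plane candidate components
#' (< \code{minCandidateVoxels}) are discarded as noise before the side
#' attribution. The declared side is the one carrying the larger summed
#' supra-threshold difference mass; confidence is its share of the total
#' (0.5 when there is no supra-threshold mass: an exactly mirrored tumor
#' cancels in the subtraction and cannot be told from a tumor-free
#' brain, the documented blind spot of the method).
#'
#' @param left,right hemisphere \linkS4class{BrainVolume}s from
#'   \code{\link{splitHemispheres}} (left stored with x increasing
#'   toward the midline, right with x increasing away from it).
#' @param params an \linkS4class{RGParams}.
#' @return An \linkS4class{AsymmetryResult}. \code{candidateRegion} is in
#'   the padded frame of the declared side (same orientation as that
#'   hemisphere's input array, lateral padding prepended for the left /
#'   appended for the right side).
#' @export
asymmetryMap <- function(left, right, params = rgParams()) {
  stopifnot(is(left, "BrainVolume"), is(right, "BrainVolume"))
  dl <- dim(left@data); dr <- dim(right@data)
  if (!all(dl[2:3] == dr[2:3]))
    stopValidation("hemisphere y/z extents differ: %s vs %s",
                   paste(dl, collapse = "x"), paste(dr, collapse = "x"))
  w <- max(dl[1], dr[1])
  padTo <- function(a, atStart) {
    need <- w - dim(a)[1]
    if (need == 0L) return(a)
    z <- array(0, c(need, dim(a)[2], dim(a)[3]))
    if (atStart) {
      out <- array(0, c(w, dim(a)[2], dim(a)[3]))
      out[(need + 1L):w, , ] <- a
      out
    } else {
      out <- array(0, c(w, dim(a)[2], dim(a)[3]))
      out[seq_len(dim(a)[1]), , ] <- a
      out
    }
  }
  # left hemisphere: midline at the high-x edge -> lateral pad at start;
  # right hemisphere: midline at the low-x edge -> lateral pad at end
  L <- padTo(left@data, atStart = TRUE)
  R <- padTo(right@data, atStart = FALSE)
  Rm <- flipX(R)  # mirrored right, aligned with L (distance from midline)
  d <- L - Rm
  # only voxels in-brain on *both* sides are comparable: at the head rim
  # a sub-voxel midline offset pairs tissue with background and would
  # swamp the difference image with an artifactual one-voxel band
  inBrain <- (L != 0) & (Rm != 0)
  adiff <- abs(d)

  dv <- d[inBrain]
  noiseScale <- if (length(dv)) 1.4826 * stats::mad(dv, constant = 1) else 0
  # floor the threshold at a tiny fraction of the intensity scale so a
  # noise-free (MAD = 0) volume is not tripped by floating-point
  # residue of the smoothing/resampling arithmetic
  intensityScale <- max(abs(L), abs(Rm), 0)
  thr <- max(params@asymmetryThreshold * noiseScale, 1e-6 * intensityScale)

  supra <- inBrain & adiff > thr
  candL <- supra & d > 0        # left brighter than its mirror
  candRmirr <- supra & d < 0    # right brighter (still in left frame)
  cleanup <- function(cand) {
    if (params@minCandidateVoxels <= 1L) return(cand)
    for (z in seq_len(dim(cand)[3])) {
      if (!any(cand[, , z])) next
      cand[, , z] <- removeSmallObjects(cand[, , z],
                                        params@minCandidateVoxels, 8L)
    }
    cand
  }
  candL <- cleanup(candL)
  candRmirr <- cleanup(candRmirr)

  massL <- sum(adiff[candL])
  massR <- sum(adiff[candRmirr])
  total <- massL + massR
  if (total == 0) {
    side <- "left"; conf <- 0.5
  } else if (massL >= massR) {
    side <- "left"; conf <- massL / total
  } else {
    side <- "right"; conf <- massR / total
  }
  cand <- if (side == "left") candL else flipX(candRmirr)

  new("AsymmetryResult",
      diffLeft = adiff, diffRight = flipX(adiff),
      tumorSide = side, candidateRegion = cand, confidence = conf,
      threshold = thr, noiseScale = noiseScale)
}
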