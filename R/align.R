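## Vertical alignment and hemisphere separation.
##
## The symmetry pipeline assumes the interhemispheric plane is a voxel
## column; "vertical alignment" finds the in-plane rotation and midline
## column that maximise the mirror similarity of the head mask, by an
## exhaustive deterministic grid search.

## Mirror-symmetry score of a 2D mask about column c: Dice-style
## 2*overlap / (non-midline mass). 1 iff perfectly symmetric about c.
mirrorScore <- function(m, c) {
  nx <- nrow(m)
  w <- min(c - 1L, nx - c)
  if (w < 1L) return(0)
  left <- m[(c - w):(c - 1L), , drop = FALSE]
  rightMirr <- m[(c + w):(c + 1L), , drop = FALSE]
  o <- sum(left & rightMirr)
  tot <- sum(m) - sum(m[c, ])
  if (tot == 0) 0 else 2 * o / tot
}

#' Align a brain volume so the hemispheres can be split vertically
#'
#' Searches rotations about the through-slice axis in [-20, +20] degrees
#' at 0.5 degree steps and candidate midline columns within the central
#' third of the x range, maximising the left-right mirror similarity of
#' the head mask (the z max-projection of non-zero voxels). Ties are
#' broken deterministically: smaller |rotation|, then smaller rotation,
#' then midline closer to the volume center, then smaller column.
#'
#' @param vol brain-extracted \linkS4class{BrainVolume} (background 0).
#' @param rotRange,rotStep rotation search half-range and step (deg).
#' @return An \linkS4class{AlignmentResult}; its \code{aligned} slot is
#'   the input resampled (nearest-neighbour, no interpolation) by the
#'   recovered rotation.
#' @examples
#' p <- makePhantom(phantomSpec(shape = c(41L, 35L, 7L),
#'                              headSemiAxes = c(16, 13, 3),
#'                              laterality = "none"))
#' alignVertical(p$volume)
#' @export
alignVertical <- function(vol, rotRange = 20, rotStep = 0.5) {
  stopifnot(is(vol, "BrainVolume"))
  dat <- vol@data
  nx <- dim(dat)[1]
  proj <- rowSums(dat != 0, dims = 2) > 0
  if (!any(proj))
    stopValidation("volume is empty (all background): cannot align")
  if (any(proj[1, ]) && any(proj[nx, ]))
    stopValidation(
      "head mask touches both x extremes: cannot bracket a midline")
  lo <- max(2L, floor(nx / 3) + 1L)
  hi <- min(nx - 1L, ceiling(2 * nx / 3))
  mids <- lo:hi
  rots <- seq(-rotRange, rotRange, by = rotStep)
  center <- (nx + 1) / 2

  best <- c(score = -Inf, rot = 0, mid = mids[1])
  better <- function(score, rot, mid) {
    eps <- 1e-12
    if (score > best["score"] + eps) return(TRUE)
    if (score < best["score"] - eps) return(FALSE)
    # deterministic tie-breaks
    if (abs(rot) < abs(best["rot"]) - eps) return(TRUE)
    if (abs(rot) > abs(best["rot"]) + eps) return(FALSE)
    if (rot < best["rot"] - eps) return(TRUE)
    if (rot > best["rot"] + eps) return(FALSE)
    dm <- abs(mid - center); dbest <- abs(best["mid"] - center)
    if (dm < dbest) return(TRUE)
    if (dm > dbest) return(FALSE)
    mid < best["mid"]
  }
  for (rot in rots) {
    mr <- rotateImageNN(proj, rot)
    for (mid in mids) {
      s <- mirrorScore(mr, mid)
      if (better(s, rot, mid)) best <- c(score = s, rot = rot, mid = mid)
    }
  }

  rot <- unname(best["rot"]); mid <- as.integer(best["mid"])
  aligned <- if (rot == 0) vol else
    brainVolume(rotateSlices(dat, rot), spacing = vol@spacing,
                sliceGap = vol@sliceGap, affine = vol@affine)
  new("AlignmentResult", rotationDeg = rot, midlineX = mid,
      aligned = aligned)
}

#' Split an aligned volume into hemispheres
#'
#' The midline column itself is excluded; the left hemisphere holds
#' columns 1..(midline-1), the right columns (midline+1)..nx, so that
#' left, midline column and right tile the aligned volume exactly.
#'
#' @param res an \linkS4class{AlignmentResult}.
#' @return list with \code{left} and \code{right}
#'   \linkS4class{BrainVolume} objects.
#' @export
splitHemispheres <- function(res) {
  stopifnot(is(res, "AlignmentResult"))
  dat <- res@aligned@data
  nx <- dim(dat)[1]
  mid <- res@midlineX
  if (mid <= 1L || mid >= nx)
    stopValidation("midline column %d lies at the volume edge", mid)
  mk <- function(a) brainVolume(a, spacing = res@aligned@spacing,
                                sliceGap = res@aligned@sliceGap)
  list(left = mk(dat[1:(mid - 1L), , , drop = FALSE]),
       right = mk(dat[(mid + 1L):nx, , , drop = FALSE]))
}
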