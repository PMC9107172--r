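## Evaluation: Dice similarity, boundary-voxel Hausdorff distance and
## volume, per tumor component, plus batch reporting.

#' Dice similarity coefficient
#'
#' 2|A ∩ B| / (|A| + |B|). By stated convention the coefficient is 1
#' when both masks are empty and 0 when exactly one is.
#'
#' @param a,b logical arrays of the same shape (any dimensionality).
#' @return scalar in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stopValidation("mask shapes differ: %s vs %s",
                   paste(dim(a), collapse = "x"),
                   paste(dim(b), collapse = "x"))
  na <- sum(a); nb <- sum(b)
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  2 * sum(a & b) / (na + nb)
}

#' Boundary voxels of a binary mask
#'
#' Foreground voxels with at least one background (or out-of-volume)
#' face neighbour: 6-connectivity faces in 3D, 4-connectivity in 2D —
#' the strictest common definition of a digital boundary.
#'
#' @param mask logical 2D or 3D array.
#' @return integer coordinate matrix, one row per boundary voxel.
#' @export
boundaryVoxels <- function(mask) {
  which(boundaryMask(mask), arr.ind = TRUE)
}

## Logical-array form of boundaryVoxels.
boundaryMask <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  stopifnot(nd %in% c(2L, 3L))
  interior <- array(TRUE, d)
  idx <- function(ax, drop1) {
    # neighbour along axis ax shifted by drop1 (+1/-1), out-of-volume = bg
    n <- array(FALSE, d)
    src <- lapply(d, seq_len)
    dst <- src
    if (drop1 > 0) { dst[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1L) }
    else { dst[[ax]] <- 1:(d[ax] - 1L); src[[ax]] <- 2:d[ax] }
    if (nd == 2L) n[dst[[1]], dst[[2]]] <- mask[src[[1]], src[[2]]]
    else n[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
    n
  }
  for (ax in seq_len(nd)) {
    interior <- interior & idx(ax, 1L) & idx(ax, -1L)
  }
  mask & !interior
}

## Directed max-min Euclidean distance between point sets (rows = mm or
## voxel coordinates), computed in chunks to bound memory.
directedHausdorff <- function(P, Q) {
  qsq <- rowSums(Q^2)
  worst <- 0
  chunk <- max(1L, floor(2e6 / nrow(Q)))
  for (s in seq(1L, nrow(P), by = chunk)) {
    idx <- s:min(nrow(P), s + chunk - 1L)
    Pp <- P[idx, , drop = FALSE]
    d2 <- outer(rowSums(Pp^2), qsq, "+") - 2 * Pp %*% t(Q)
    mins <- d2[cbind(seq_len(nrow(d2)),
                     max.col(-d2, ties.method = "first"))]
    worst <- max(worst, max(mins))
  }
  sqrt(max(worst, 0))
}

#' Symmetric boundary Hausdorff distance
#'
#' H(A, B) = max of the two directed max-min Euclidean distances
#' between the boundary voxels of the two masks. Distances are in voxel
#' units by default; when \code{spacing} is supplied they are in mm,
#' with the effective through-slice step \code{dz + sliceGap}
#' (center-to-center distance of non-contiguous slices).
#'
#' @param a,b logical arrays of the same shape, both non-empty.
#' @param spacing optional mm voxel spacing (length matching the array
#'   dimensionality).
#' @param sliceGap mm slice gap added to dz for 3D mm distances.
#' @return scalar distance >= 0.
#' @examples
#' a <- array(FALSE, c(5, 5, 1)); b <- a
#' a[1, 1, 1] <- TRUE; b[4, 5, 1] <- TRUE
#' hausdorffDistance(a, b)  # 3-4-5 triangle -> 5
#' @export
hausdorffDistance <- function(a, b, spacing = NULL, sliceGap = 0) {
  if (!all(dim(a) == dim(b)))
    stopValidation("mask shapes differ: %s vs %s",
                   paste(dim(a), collapse = "x"),
                   paste(dim(b), collapse = "x"))
  if (sum(a) == 0 || sum(b) == 0)
    stopValidation(paste("Hausdorff distance is undefined for an empty mask;",
                         "record this case as 'undefined' in the report"))
  P <- boundaryVoxels(a) * 1.0
  Q <- boundaryVoxels(b) * 1.0
  if (!is.null(spacing)) {
    sp <- as.numeric(spacing)
    if (length(sp) != ncol(P))
      stopValidation("spacing length %d does not match %dD masks",
                     length(sp), ncol(P))
    if (ncol(P) == 3L) sp[3] <- sp[3] + sliceGap
    P <- sweep(P, 2, sp, "*")
    Q <- sweep(Q, 2, sp, "*")
  }
  max(directedHausdorff(P, Q), directedHausdorff(Q, P))
}

#' Volume of a binary mask
#'
#' The voxel count, and the physical volume count * dx * dy * dz when
#' spacing is given. The slice gap is never folded into mm^3 (tissue in
#' the gap was not imaged); it is reported as a caveat instead.
#'
#' @param mask logical array.
#' @param spacing optional mm voxel spacing.
#' @param sliceGap mm slice gap (caveat only).
#' @return list with \code{voxels}, \code{mm3} (NA without spacing) and
#'   \code{gapCaveat} (TRUE when a non-zero slice gap was present and
#'   excluded).
#' @export
maskVolume <- function(mask, spacing = NULL, sliceGap = 0) {
  v <- sum(mask)
  mm3 <- if (is.null(spacing)) NA_real_ else v * prod(as.numeric(spacing))
  list(voxels = v, mm3 = mm3, gapCaveat = !is.null(spacing) && sliceGap > 0)
}

#' Evaluate a predicted tumor mask against ground truth
#'
#' Computes Dice, boundary Hausdorff (voxel and mm) and volumes (voxels
#' and mm^3) for the whole tumor (labels >= 1), edema (label 2) and
#' necrotic core (label 1). Components a method does not produce (an
#' undifferentiated whole-tumor-only prediction) are reported as
#' "not_produced"; a Hausdorff involving an empty mask is reported as
#' undefined rather than a number. Conventions (both-empty Dice = 1,
#' undefined Hausdorff, slice gap excluded from mm^3) are attached as
#' the "conventions" attribute of the report.
#'
#' @param pred,gt \linkS4class{TumorMask} objects on the same geometry.
#' @param case case identifier for the report rows.
#' @return data.frame with one row per component and columns case,
#'   component, dsc, hausdorff_voxels, hausdorff_mm, vol_pred_voxels,
#'   vol_gt_voxels, vol_pred_mm3, vol_gt_mm3, flags.
#' @export
evaluateSegmentation <- function(pred, gt, case = "case") {
  stopifnot(is(pred, "TumorMask"), is(gt, "TumorMask"))
  geo <- checkGeometryCompatible(pred, gt)
  if (!geo$compatible)
    stopValidation("prediction and ground truth are not geometry-compatible: %s",
                   paste(geo$mismatches, collapse = "; "))
  sp <- gt@spacing; gap <- gt@sliceGap
  comps <- c("whole_tumor", "edema", "necrotic")
  rows <- lapply(comps, function(cp) {
    flags <- character(0)
    if (pred@undifferentiated && cp != "whole_tumor") {
      flags <- "not_produced"
      return(data.frame(case = case, component = cp, dsc = NA_real_,
                        hausdorff_voxels = NA_real_, hausdorff_mm = NA_real_,
                        vol_pred_voxels = NA_real_,
                        vol_gt_voxels = sum(componentMask(gt, cp)),
                        vol_pred_mm3 = NA_real_,
                        vol_gt_mm3 = sum(componentMask(gt, cp)) * prod(sp),
                        flags = flags, stringsAsFactors = FALSE))
    }
    pm <- componentMask(pred, cp); gm <- componentMask(gt, cp)
    dsc <- diceCoefficient(pm, gm)
    if (sum(pm) > 0 && sum(gm) > 0) {
      hv <- hausdorffDistance(pm, gm)
      hm <- hausdorffDistance(pm, gm, spacing = sp, sliceGap = gap)
    } else {
      hv <- NA_real_; hm <- NA_real_
      flags <- c(flags, "hausdorff_undefined")
    }
    if (gap > 0) flags <- c(flags, "slice_gap_excluded_from_mm3")
    data.frame(case = case, component = cp, dsc = dsc,
               hausdorff_voxels = hv, hausdorff_mm = hm,
               vol_pred_voxels = sum(pm), vol_gt_voxels = sum(gm),
               vol_pred_mm3 = sum(pm) * prod(sp),
               vol_gt_mm3 = sum(gm) * prod(sp),
               flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "conventions") <- paste(
    "Dice = 1 when both masks are empty, 0 when exactly one is;",
    "Hausdorff is undefined (NA, flagged) when either mask is empty;",
    "mm^3 volumes exclude the slice gap (unimaged tissue).")
  out
}

#' Aggregate evaluation over multiple cases
#'
#' Binds the per-case component reports and appends one mean row per
#' component (case = "mean"). Rows with undefined Hausdorff or
#' not-produced components are excluded from the affected means;
#' \code{n_hausdorff_excluded} counts the exclusions.
#'
#' @param cases non-empty list; each element either an evaluation
#'   data.frame from \code{\link{evaluateSegmentation}} or a list with
#'   elements \code{pred}, \code{gt} and optionally \code{case}.
#' @return data.frame in the same layout plus the mean rows and the
#'   \code{n_hausdorff_excluded} column.
#' @export
batchReport <- function(cases) {
  if (length(cases) == 0L)
    stopValidation("batch report needs at least one case")
  reports <- lapply(seq_along(cases), function(i) {
    x <- cases[[i]]
    if (is.data.frame(x)) return(x)
    evaluateSegmentation(x$pred, x$gt,
                         case = if (!is.null(x$case)) x$case
                                else paste0("case", i))
  })
  tab <- do.call(rbind, reports)
  tab$n_hausdorff_excluded <- NA_integer_
  means <- lapply(unique(tab$component), function(cp) {
    sub <- tab[tab$component == cp, ]
    nexcl <- sum(is.na(sub$hausdorff_voxels))
    data.frame(case = "mean", component = cp,
               dsc = mean(sub$dsc, na.rm = TRUE),
               hausdorff_voxels = mean(sub$hausdorff_voxels, na.rm = TRUE),
               hausdorff_mm = mean(sub$hausdorff_mm, na.rm = TRUE),
               vol_pred_voxels = mean(sub$vol_pred_voxels, na.rm = TRUE),
               vol_gt_voxels = mean(sub$vol_gt_voxels, na.rm = TRUE),
               vol_pred_mm3 = mean(sub$vol_pred_mm3, na.rm = TRUE),
               vol_gt_mm3 = mean(sub$vol_gt_mm3, na.rm = TRUE),
               flags = "", n_hausdorff_excluded = nexcl,
               stringsAsFactors = FALSE)
  })
  rbind(tab, do.call(rbind, means))
}
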