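#' Construct a BrainVolume
#'
#' @param data 3D numeric array.
#' @param spacing voxel size (dx, dy, dz) in mm.
#' @param sliceGap mm gap between acquired slices (default 0).
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a
#'   diagonal scaling by the center-to-center spacing.
#' @return A \linkS4class{BrainVolume}.
#' @export
brainVolume <- function(data, spacing = c(1, 1, 1), sliceGap = 0,
                        affine = NULL) {
  if (is.null(affine))
    affine <- diag(c(spacing[1], spacing[2], spacing[3] + sliceGap, 1))
  new("BrainVolume", data = as.array(data) * 1.0,
      spacing = as.numeric(spacing), sliceGap = as.numeric(sliceGap),
      affine = affine)
}

#' Construct a TumorMask
#'
#' @param labels 3D integer-valued array with labels in \{0, 1, 2\}.
#' @param spacing,sliceGap geometry (mm).
#' @param undifferentiated TRUE when only the whole tumor is encoded.
#' @return A \linkS4class{TumorMask}.
#' @export
tumorMask <- function(labels, spacing = c(1, 1, 1), sliceGap = 0,
                      undifferentiated = FALSE) {
  storage.mode(labels) <- "integer"
  new("TumorMask", labels = labels, spacing = as.numeric(spacing),
      sliceGap = as.numeric(sliceGap), undifferentiated = undifferentiated)
}

#' @rdname accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))
#' @rdname accessors
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("sliceGap", function(x) standardGeneric("sliceGap"))
#' @rdname accessors
#' @export
setGeneric("wholeTumor", function(x) standardGeneric("wholeTumor"))
#' @rdname accessors
#' @export
setGeneric("componentMask", function(x, component) standardGeneric("componentMask"))
#' @rdname accessors
#' @export
setGeneric("tumorMaskOf", function(x) standardGeneric("tumorMaskOf"))

#' Accessors for gliomaSeg objects
#'
#' \code{imgData}/\code{maskLabels} return the raw arrays;
#' \code{voxelSpacing} and \code{sliceGap} the geometry; \code{wholeTumor}
#' the logical union mask (labels >= 1); \code{componentMask} the logical
#' mask of one component ("whole_tumor", "edema" or "necrotic");
#' \code{tumorMaskOf} extracts the \linkS4class{TumorMask} from a
#' segmentation result.
#'
#' @param x the object.
#' @param component one of "whole_tumor", "edema", "necrotic".
#' @name accessors
NULL

#' @rdname accessors
setMethod("imgData", "BrainVolume", function(x) x@data)
#' @rdname accessors
setMethod("maskLabels", "TumorMask", function(x) x@labels)
#' @rdname accessors
setMethod("voxelSpacing", "BrainVolume", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "TumorMask", function(x) x@spacing)
#' @rdname accessors
setMethod("sliceGap", "BrainVolume", function(x) x@sliceGap)
#' @rdname accessors
setMethod("sliceGap", "TumorMask", function(x) x@sliceGap)
#' @rdname accessors
setMethod("wholeTumor", "TumorMask", function(x) x@labels >= 1L)
#' @rdname accessors
setMethod("componentMask", "TumorMask", function(x, component) {
  switch(component,
         whole_tumor = x@labels >= 1L,
         edema = x@labels == 2L,
         necrotic = x@labels == 1L,
         stopValidation("unknown component '%s'", component))
})
#' @rdname accessors
setMethod("tumorMaskOf", "RGSegmentation", function(x) x@mask)

setMethod("show", "BrainVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("BrainVolume %d x %d x %d, spacing %s mm, slice gap %g mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x "),
              object@sliceGap))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "TumorMask", function(object) {
  d <- dim(object@labels)
  cat(sprintf("TumorMask %d x %d x %d (%s)\n", d[1], d[2], d[3],
              if (object@undifferentiated) "whole tumor only"
              else "component labels"))
  cat(sprintf("  voxels: necrotic %d, edema %d, whole tumor %d\n",
              sum(object@labels == 1L), sum(object@labels == 2L),
              sum(object@labels >= 1L)))
})

setMethod("show", "FCMFit", function(object) {
  cat(sprintf("FCMFit: %d clusters, %d points, %d iterations (%s)\n",
              length(object@centroids), nrow(object@memberships),
              object@nIter,
              if (object@converged) "converged" else "not converged"))
  cat("  centroids:", paste(format(object@centroids, digits = 5),
                            collapse = ", "), "\n")
  cat(sprintf("  final cost J = %g\n", object@cost))
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult: rotation %.1f deg, midline column %d\n",
              object@rotationDeg, object@midlineX))
})

setMethod("show", "AsymmetryResult", function(object) {
  cat(sprintf("AsymmetryResult: tumor side %s (confidence %.3f)\n",
              object@tumorSide, object@confidence))
  cat(sprintf("  %d candidate voxels above %.4g (noise scale %.4g)\n",
              sum(object@candidateRegion), object@threshold,
              object@noiseScale))
})

setMethod("show", "RGSegmentation", function(object) {
  cat(sprintf("RGSegmentation: side %s, confidence %.3f%s\n",
              object@tumorSide, object@confidence,
              if (object@bilateralSuspect) " [bilateral-suspect]" else ""))
  cat(sprintf("  alignment: rotation %.1f deg, midline %d; %d slice(s) grown\n",
              object@rotationDeg, object@midlineX,
              length(object@slicesProcessed)))
  cat(sprintf("  whole-tumor voxels: %d\n", sum(object@mask@labels >= 1L)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec %s, spacing %s mm (gap %g), laterality %s\n",
              paste(object@shape, collapse = " x "),
              paste(format(object@spacing, digits = 3), collapse = " x "),
              object@sliceGap, object@laterality))
  cat(sprintf("  noise sigma %g, bias %g, rotation %g deg, seed %d\n",
              object@noiseSigma, object@biasAmplitude, object@rotationDeg,
              object@seed))
})
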