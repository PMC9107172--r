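## NIfTI input/output and geometry checks.
##
## Volumes are normalised on load to the fixed anatomical axis order
## used by the symmetry operations: x = left-right, y = posterior-
## anterior, z = inferior-superior ("RAS"). No resampling is ever done
## on load: clinical volumes with non-contiguous slices are processed at
## native resolution and the slice gap is carried as metadata only.

#' Read a 3D NIfTI volume
#'
#' Loads a NIfTI-1/NIfTI-2 image, reorients it to the package's RAS axis
#' convention via the header transform, and casts intensities to double.
#' The z header spacing (pixdim) is treated as the center-to-center
#' slice spacing; when the acquired slice thickness is supplied the
#' slice gap is recovered as \code{spacing - thickness} and \code{dz}
#' is set to the thickness.
#'
#' @param path path to a .nii or .nii.gz file.
#' @param sliceThickness optional acquired slice thickness in mm; must
#'   not exceed the header slice spacing.
#' @return A \linkS4class{BrainVolume}.
#' @examples
#' v <- makePhantom(phantomSpec(shape = c(21L, 19L, 5L),
#'                              headSemiAxes = c(8, 7, 2),
#'                              laterality = "none"))$volume
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(v, f)
#' readVolume(f)
#' @export
readVolume <- function(path, sliceThickness = NULL) {
  if (!file.exists(path))
    stopValidation("file does not exist: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stopValidation("not a readable NIfTI file (%s): %s",
                                   conditionMessage(e), path))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1, drop = TRUE]
  } else if (length(d) != 3L) {
    stopValidation(
      "expected a 3D volume but got %dD data (extra dimension(s) of size %s): %s",
      length(d), paste(d[-(1:3)], collapse = ", "), path)
  }
  img <- RNifti::asNifti(img)
  ornt <- try(RNifti::orientation(img), silent = TRUE)
  if (!inherits(ornt, "try-error") && !is.na(ornt) && ornt != "RAS")
    RNifti::orientation(img) <- "RAS"
  dat <- array(as.numeric(img), dim(img))
  n_nan <- sum(is.nan(dat))
  if (n_nan > 0)
    stopValidation("volume contains %d NaN voxel(s): %s", n_nan, path)
  sp <- abs(RNifti::pixdim(img))[1:3]
  gap <- 0
  if (!is.null(sliceThickness)) {
    if (sliceThickness <= 0 || sliceThickness > sp[3] + 1e-9)
      stopValidation(
        "sliceThickness (%g mm) must be positive and <= the header slice spacing (%g mm)",
        sliceThickness, sp[3])
    gap <- sp[3] - sliceThickness
    sp[3] <- sliceThickness
  }
  aff <- RNifti::xform(img)
  attributes(aff) <- list(dim = dim(aff))
  brainVolume(dat, spacing = sp, sliceGap = gap, affine = aff)
}

#' Read a tumor label mask
#'
#' Decodes a NIfTI label volume, validates labels against the
#' \{0 background, 1 necrotic, 2 edema\} encoding and checks the shape
#' against a reference volume. Non-integer voxel values are rejected
#' rather than rounded.
#'
#' @param path path to the mask file.
#' @param reference \linkS4class{BrainVolume} providing geometry.
#' @return A \linkS4class{TumorMask}.
#' @export
readMask <- function(path, reference) {
  stopifnot(is(reference, "BrainVolume"))
  vol <- readVolume(path, sliceThickness = NULL)
  dat <- vol@data
  if (any(dat != round(dat)))
    stopValidation("mask file holds non-integer values: %s", path)
  bad <- setdiff(unique(as.vector(dat)), c(0, 1, 2))
  if (length(bad))
    stopValidation("mask holds unknown label value(s) %s (allowed: 0, 1, 2): %s",
                   paste(sort(bad), collapse = ", "), path)
  if (!all(dim(dat) == dim(reference@data)))
    stopValidation("mask shape (%s) does not match reference shape (%s)",
                   paste(dim(dat), collapse = "x"),
                   paste(dim(reference@data), collapse = "x"))
  tumorMask(dat, spacing = reference@spacing, sliceGap = reference@sliceGap)
}

#' Write a volume or mask to NIfTI
#'
#' Masks are written as int16 so that a write/read round trip reproduces
#' labels bit-exactly; volumes are written as float64. The stored z
#' pixdim is the center-to-center spacing \code{dz + sliceGap}.
#'
#' @param mask a \linkS4class{TumorMask}.
#' @param vol a \linkS4class{BrainVolume}.
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "TumorMask"))
  validObject(mask)
  img <- RNifti::asNifti(mask@labels)
  RNifti::pixdim(img) <- c(mask@spacing[1:2], mask@spacing[3] + mask@sliceGap)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname writeMask
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "BrainVolume"))
  validObject(vol)
  img <- RNifti::asNifti(vol@data)
  RNifti::pixdim(img) <- c(vol@spacing[1:2], vol@spacing[3] + vol@sliceGap)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Check two volumes for geometric compatibility
#'
#' Algorithms that combine volumes (and the evaluation module) require
#' equal matrix dimensions and voxel spacings; this reproduces the
#' dimension-matching constraint hit when mixing acquisitions of
#' different matrix sizes. Always returns a report, never throws.
#'
#' @param a,b \linkS4class{BrainVolume} or \linkS4class{TumorMask}
#'   objects.
#' @param tol spacing tolerance in mm (default 1e-3).
#' @return list with \code{compatible} (logical) and \code{mismatches}
#'   (character vector describing each differing attribute).
#' @examples
#' p <- makePhantom(phantomSpec(shape = c(21L, 19L, 5L),
#'                              headSemiAxes = c(8, 7, 2),
#'                              laterality = "none"))
#' checkGeometryCompatible(p$volume, p$volume)
#' @export
checkGeometryCompatible <- function(a, b, tol = 1e-3) {
  arr <- function(x) if (is(x, "TumorMask")) x@labels else x@data
  da <- dim(arr(a)); db <- dim(arr(b))
  mism <- character(0)
  if (!all(da == db))
    mism <- c(mism, sprintf("shape: %s vs %s",
                            paste(da, collapse = "x"),
                            paste(db, collapse = "x")))
  ax <- c("dx", "dy", "dz")
  for (i in 1:3)
    if (abs(a@spacing[i] - b@spacing[i]) > tol)
      mism <- c(mism, sprintf("%s: %g vs %g mm", ax[i],
                              a@spacing[i], b@spacing[i]))
  if (abs(a@sliceGap - b@sliceGap) > tol)
    mism <- c(mism, sprintf("slice gap: %g vs %g mm", a@sliceGap, b@sliceGap))
  list(compatible = length(mism) == 0L, mismatches = mism)
}
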