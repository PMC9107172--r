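## Synthetic brain phantom generator with ground-truth labels.
##
## The phantom emulates what the segmentation pipelines rely on — a
## skull-stripped head with symmetric hemispheres, a two-compartment
## tumor (necrotic core inside an edema shell) confined to one
## hemisphere or mirrored into both, FLAIR-like tissue contrast,
## additive Gaussian noise inside the brain, a smooth multiplicative
## bias field, and both isotropic and clinical-style non-contiguous
## slice geometries. It does not emulate cortical folding, tissue
## texture or acquisition physics.

#' Construct a phantom specification
#'
#' Defaults describe a scaled-down isotropic volume with an odd
#' in-plane matrix (so the interhemispheric plane falls exactly on a
#' voxel column) and FLAIR-like tissue contrast. See
#' \linkS4class{PhantomSpec} for field meanings.
#'
#' @param shape,spacing,sliceGap volume geometry.
#' @param headSemiAxes head ellipsoid semi-axes in voxels.
#' @param tissueIntensities named means for background, brain,
#'   necrotic, edema.
#' @param noiseSigma,biasAmplitude,rotationDeg,seed corruption
#'   parameters.
#' @param tumorCenter,coreRadius,edemaRadius,laterality tumor
#'   placement; radii are in-plane voxel radii, the through-slice
#'   semi-axis is derived from the physical radius and the effective
#'   slice spacing (at least one slice).
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(shape = c(101L, 91L, 24L), spacing = c(1, 1, 1),
                        sliceGap = 0, headSemiAxes = c(42, 36, 11),
                        tissueIntensities = c(background = 0, brain = 120,
                                              necrotic = 160, edema = 200),
                        noiseSigma = 0, biasAmplitude = 0,
                        tumorCenter = c(30, 46, 12), coreRadius = 4,
                        edemaRadius = 8, laterality = "left",
                        rotationDeg = 0, seed = 1) {
  new("PhantomSpec", shape = as.integer(shape), spacing = as.numeric(spacing),
      sliceGap = as.numeric(sliceGap), headSemiAxes = as.numeric(headSemiAxes),
      tissueIntensities = tissueIntensities, noiseSigma = noiseSigma,
      biasAmplitude = biasAmplitude, tumorCenter = as.numeric(tumorCenter),
      coreRadius = coreRadius, edemaRadius = edemaRadius,
      laterality = laterality, rotationDeg = rotationDeg,
      seed = as.integer(seed))
}

## Logical ellipsoid on the voxel lattice.
ellipsoidMask <- function(shape, center, semi) {
  x <- (seq_len(shape[1]) - center[1]) / semi[1]
  y <- (seq_len(shape[2]) - center[2]) / semi[2]
  z <- (seq_len(shape[3]) - center[3]) / semi[3]
  o <- outer(outer(x^2, y^2, "+"), z^2, "+")
  o <= 1
}

#' Generate a synthetic brain phantom with ground truth
#'
#' Builds the head ellipsoid at brain intensity, inserts the tumor as
#' concentric ellipsoids (core -> label 1 at necrotic intensity, shell
#' -> label 2 at edema intensity), applies the multiplicative bias
#' field, rotates in-plane (nearest neighbour, labels included), adds
#' Gaussian noise inside the head, and re-zeroes the background as
#' skull stripping would. \code{laterality = "right"} and the mirrored
#' second tumor of \code{"bilateral_mirrored"} are produced by exact
#' left-right array mirroring of the left-hemisphere construction, so
#' left and right phantoms are exact flips of one another.
#' Deterministic given the seed.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with \code{volume} (\linkS4class{BrainVolume}),
#'   \code{mask} (ground-truth \linkS4class{TumorMask}) and
#'   \code{spec}.
#' @export
makePhantom <- function(spec = phantomSpec()) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  sh <- spec@shape
  headCenter <- (sh + 1) / 2
  head <- ellipsoidMask(sh, headCenter, spec@headSemiAxes)
  if (!any(head)) stopValidation("head ellipsoid contains no voxels")

  labels <- array(0L, sh)
  if (spec@laterality != "none") {
    dzEff <- spec@spacing[3] + spec@sliceGap
    zsemi <- function(r) max(1, r * spec@spacing[1] / dzEff)
    core <- ellipsoidMask(sh, spec@tumorCenter,
                          c(spec@coreRadius, spec@coreRadius,
                            zsemi(spec@coreRadius)))
    edema <- ellipsoidMask(sh, spec@tumorCenter,
                           c(spec@edemaRadius, spec@edemaRadius,
                             zsemi(spec@edemaRadius)))
    if (any(edema & !head))
      stopValidation("tumor protrudes outside the head ellipsoid")
    labels[edema] <- 2L
    labels[core] <- 1L
    if (spec@laterality == "right") {
      labels <- flipX(labels)
    } else if (spec@laterality == "bilateral_mirrored") {
      labels <- pmax(labels, flipX(labels))
    }
    # "left" and "midline" use the center as given
  }

  ti <- spec@tissueIntensities
  dat <- array(ti[["background"]], sh)
  dat[head] <- ti[["brain"]]
  dat[labels == 2L] <- ti[["edema"]]
  dat[labels == 1L] <- ti[["necrotic"]]

  if (spec@biasAmplitude > 0) {
    q <- function(n) ((seq_len(n) / n) - 0.35)^2
    F <- outer(outer(q(sh[1]), q(sh[2])), q(sh[3]))
    # normalise over the head so the peak fractional deviation inside
    # the brain is exactly the requested amplitude
    F <- F - mean(F[head])
    B <- 1 + spec@biasAmplitude * F / max(abs(F[head]))
    dat[head] <- dat[head] * B[head]
  }

  if (spec@rotationDeg != 0) {
    dat <- rotateSlices(dat, spec@rotationDeg)
    labels <- rotateSlices(labels, spec@rotationDeg)
    head <- rotateSlices(head * 1L, spec@rotationDeg) == 1L
  }

  if (spec@noiseSigma > 0) {
    set.seed(spec@seed)
    n <- sum(head)
    dat[head] <- dat[head] + stats::rnorm(n, sd = spec@noiseSigma)
  }
  dat[!head] <- ti[["background"]]

  list(volume = brainVolume(dat, spacing = spec@spacing,
                            sliceGap = spec@sliceGap),
       mask = tumorMask(labels, spacing = spec@spacing,
                        sliceGap = spec@sliceGap),
       spec = spec)
}

#' Clinical-style low-resolution phantom preset
#'
#' Convenience preset for an anisotropic, non-contiguous acquisition:
#' in-plane 256 x 224 at 0.5 x 0.5 mm (scaled down from a full clinical
#' matrix for desk-scale speed), 20 slices of 5 mm thickness with a
#' 1.5 mm inter-slice gap (6.5 mm center-to-center). Any
#' \code{\link{phantomSpec}} argument can be overridden, e.g.
#' \code{spacing = c(1, 1, 1), sliceGap = 0} for an isotropic
#' BRATS-like phantom.
#'
#' @param ... overrides passed to \code{\link{phantomSpec}}.
#' @return As \code{\link{makePhantom}}.
#' @export
makeClinicalPhantom <- function(...) {
  defaults <- list(shape = c(256L, 224L, 20L), spacing = c(0.5, 0.5, 5),
                   sliceGap = 1.5, headSemiAxes = c(105, 90, 8),
                   tumorCenter = c(72, 112, 10), coreRadius = 10,
                   edemaRadius = 24)
  over <- list(...)
  args <- utils::modifyList(defaults, over)
  makePhantom(do.call(phantomSpec, args))
}

#' Canonical phantom test suite
#'
#' Six deterministic fixtures on the clinical-style geometry covering
#' the scenarios the pipelines must handle:
#' \describe{
#'   \item{symmetric_clean}{tumor-free, noise-free: the symmetry fixed
#'     point.}
#'   \item{unilateral_LGG_like}{large edema shell, small core,
#'     noise-free.}
#'   \item{unilateral_HGG_like}{large necrotic core, moderate noise
#'     (sigma 8, edema-brain contrast-to-noise 10).}
#'   \item{bilateral_mirrored}{identical mirrored tumors in both
#'     hemispheres, noise-free: mirrored subtraction cancels — the
#'     region-growing blind spot.}
#'   \item{rotated_7deg}{unilateral tumor with a +7 degree in-plane
#'     rotation, for alignment recovery.}
#'   \item{noisy_biased}{unilateral tumor with noise and a 20% smooth
#'     multiplicative bias field.}
#' }
#'
#' @param seed base RNG seed; each fixture derives its own offset seed.
#' @return named list of \code{\link{makePhantom}} results.
#' @export
phantomSuite <- function(seed = 1) {
  seed <- as.integer(seed) %% 1000000L
  list(
    symmetric_clean = makeClinicalPhantom(laterality = "none",
                                          seed = seed + 1L),
    # edema radius chosen so the ellipsoid tip falls *between* slice
    # centers: a tip exactly on a slice center yields a 1-voxel tissue
    # class on that slice, which no intensity clustering can represent
    unilateral_LGG_like = makeClinicalPhantom(coreRadius = 7,
                                              edemaRadius = 25,
                                              seed = seed + 2L),
    unilateral_HGG_like = makeClinicalPhantom(coreRadius = 16,
                                              edemaRadius = 24,
                                              noiseSigma = 8,
                                              seed = seed + 3L),
    bilateral_mirrored = makeClinicalPhantom(laterality = "bilateral_mirrored",
                                             seed = seed + 4L),
    rotated_7deg = makeClinicalPhantom(rotationDeg = 7, seed = seed + 5L),
    noisy_biased = makeClinicalPhantom(noiseSigma = 8, biasAmplitude = 0.2,
                                       seed = seed + 6L))
}
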