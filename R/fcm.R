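## Fuzzy C-means clustering on voxel intensities, slice-wise tumor
## extraction and small-object cleanup.
##
## The solver minimises the fuzzy within-cluster cost
##   J = sum_j sum_i w_ij^m (x_j - c_i)^2
## by alternating the centroid update (w^m-weighted mean) with the
## standard membership update
##   w_ij = 1 / sum_k (|x_j - c_i| / |x_j - c_k|)^(2/(m-1)),
## the stationarity condition of J under the sum-to-one constraint.

#' Fuzzy C-means parameters
#'
#' See \linkS4class{FCMParams} for the meaning of each field. The
#' default C = 4 accommodates a background-like class, normal brain,
#' necrotic core and edema on FLAIR-like intensities.
#'
#' @param C number of clusters.
#' @param m fuzziness exponent (> 1).
#' @param tol convergence threshold on the max centroid change.
#' @param maxIter iteration cap.
#' @param seed RNG seed for the optional random initialisation.
#' @param init "range" (deterministic) or "random".
#' @param minArea small-object cleanup area (voxels).
#' @param connectivity cleanup connectivity, 4 or 8.
#' @param minSeparation tumor-presence separation factor (noise-scale
#'   multiples); see \linkS4class{FCMParams}.
#' @return An \linkS4class{FCMParams}.
#' @export
fcmParams <- function(C = 4, m = 2, tol = 1e-5, maxIter = 200, seed = 1,
                      init = "range", minArea = 20, connectivity = 8,
                      minSeparation = 4) {
  new("FCMParams", nClusters = as.integer(C), m = m, tol = tol,
      maxIter = as.integer(maxIter), seed = as.integer(seed), init = init,
      minArea = as.integer(minArea), connectivity = as.integer(connectivity),
      minSeparation = minSeparation)
}

## Membership update for given centroids; handles points coincident with
## one or more centroids (membership split equally among them).
fcmMemberships <- function(values, centroids, m) {
  D <- abs(outer(values, centroids, "-"))
  zero <- D < .Machine$double.eps
  anyZero <- rowSums(zero) > 0
  P <- D^(-2 / (m - 1))
  W <- P / rowSums(P)
  if (any(anyZero)) {
    W[anyZero, ] <- zero[anyZero, , drop = FALSE] /
      rowSums(zero[anyZero, , drop = FALSE])
  }
  W
}

#' Fuzzy C-means clustering of a 1D intensity sample
#'
#' Alternating optimisation of centroids (fuzzy weighted means) and
#' memberships (standard reciprocal-distance-ratio update) until the
#' largest centroid displacement falls below \code{tol} or the
#' iteration cap is reached. Centroids are returned sorted ascending
#' with membership columns permuted to match. Initialisation is
#' deterministic by default: C centroids evenly spaced over the data
#' range, which separates minority intensity modes that quantile-based
#' starts collapse onto the dominant tissue mode.
#'
#' @param values numeric vector of N intensities (N >= C, all finite).
#' @param params an \linkS4class{FCMParams}.
#' @return An \linkS4class{FCMFit}. When all values are identical and
#'   C >= 2 the problem is degenerate: one centroid sits at that value,
#'   the remaining clusters are flagged empty and \code{converged} is
#'   FALSE.
#' @examples
#' fit <- fcmCluster(c(rep(10, 50), rep(90, 50)), fcmParams(C = 2))
#' fit@centroids
#' @export
fcmCluster <- function(values, params = fcmParams()) {
  stopifnot(is(params, "FCMParams"))
  validObject(params)
  values <- as.numeric(values)
  N <- length(values); C <- params@nClusters; m <- params@m
  if (any(!is.finite(values)))
    stopValidation("values must all be finite")
  if (N < C)
    stopValidation("need at least C = %d data points, got %d", C, N)

  rng <- range(values)
  if (rng[1] == rng[2] && C >= 2L) {
    W <- matrix(0, N, C); W[, 1] <- 1
    return(new("FCMFit",
               centroids = c(rng[1], rep(NA_real_, C - 1L)),
               memberships = W, cost = 0, costTrace = numeric(0),
               nIter = 0L, converged = FALSE,
               empty = c(FALSE, rep(TRUE, C - 1L))))
  }

  if (C == 1L) {
    ctr <- mean(values)
    W <- matrix(1, N, 1L)
    J <- sum((values - ctr)^2)
    return(new("FCMFit", centroids = ctr, memberships = W, cost = J,
               costTrace = J, nIter = 1L, converged = TRUE, empty = FALSE))
  }

  centroids <- switch(params@init,
    range = rng[1] + (seq_len(C) - 0.5) / C * (rng[2] - rng[1]),
    random = {
      set.seed(params@seed)
      sort(sample(unique(values), C))
    })

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  W <- NULL
  for (iter in seq_len(params@maxIter)) {
    W <- fcmMemberships(values, centroids, m)
    Wm <- W^m
    den <- colSums(Wm)
    newC <- ifelse(den > 0, colSums(Wm * values) / den, centroids)
    trace <- c(trace, fcmCost(values, newC, W, m))
    delta <- max(abs(newC - centroids))
    centroids <- newC
    if (delta < params@tol) { converged <- TRUE; break }
  }
  W <- fcmMemberships(values, centroids, m)

  ord <- order(centroids)
  centroids <- centroids[ord]
  W <- W[, ord, drop = FALSE]
  hard <- max.col(W, ties.method = "last")
  empty <- tabulate(hard, nbins = C) == 0L
  J <- fcmCost(values, centroids, W, m)
  new("FCMFit", centroids = centroids, memberships = W, cost = J,
      costTrace = c(trace, J), nIter = iter, converged = converged,
      empty = empty)
}

#' Fuzzy within-cluster cost
#'
#' The double sum J = sum_j sum_i w_ij^m (x_j - c_i)^2, exactly as the
#' solver minimises it; also usable as an independent check on a fitted
#' state. Clusters with NA centroids (flagged empty) contribute 0.
#'
#' @param values numeric(N) data points.
#' @param centroids numeric(C).
#' @param memberships N x C membership matrix.
#' @param m fuzziness exponent.
#' @return the scalar cost J >= 0.
#' @export
fcmCost <- function(values, centroids, memberships, m) {
  N <- length(values); C <- length(centroids)
  if (!is.matrix(memberships) || nrow(memberships) != N ||
      ncol(memberships) != C)
    stopValidation("memberships must be a %d x %d matrix", N, C)
  keep <- !is.na(centroids)
  D2 <- outer(values, centroids[keep], "-")^2
  sum(memberships[, keep, drop = FALSE]^m * D2)
}

#' Remove small connected components from a binary slice
#'
#' Area opening: in-plane connected components (4- or 8-connectivity)
#' smaller than \code{minArea} voxels are deleted; larger components are
#' untouched. Idempotent, and monotone in \code{minArea}.
#'
#' @param mask logical matrix.
#' @param minArea minimum component size kept (0 or 1 = identity).
#' @param connectivity 4 or 8.
#' @return logical matrix.
#' @export
removeSmallObjects <- function(mask, minArea, connectivity = 8L) {
  if (minArea <= 1L || !any(mask)) return(mask)
  lab <- labelComponents2D(mask, as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minArea)
  mask & matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Hard-assign clusters on a slice and map them to tumor components
#'
#' Each in-brain voxel is assigned to its maximum-membership cluster
#' (ties to the higher centroid). Because the solver may spread one
#' tissue mode over several clusters (typically the heavy normal-brain
#' mode, occasionally edema), adjacent clusters whose centroid gap sits
#' at the noise level (below \code{minSeparation} times the robust MAD
#' noise scale of the bottom cluster) are first merged into tissue
#' groups. The top group becomes edema (label 2, the brightest tissue
#' on FLAIR); the highest cluster of the group immediately below is
#' relabelled necrotic (label 1) where its voxels fall inside the
#' filled convex hull of the slice's edema pixels, i.e. within the
#' tumor territory; everything else maps to background. When all
#' clusters fall into a single group the slice carries no tissue that
#' stands clear of the noise — a tumor-free slice — and is returned
#' unlabelled; without this test the brightest noise band would
#' masquerade as edema. With \code{mode = "whole"} (allowed for
#' C >= 2) only the edema group is emitted, as label 2.
#'
#' @param sliceImg numeric matrix of the clustered slice (provides the
#'   shape and the intensities for the tumor-presence test).
#' @param fit \linkS4class{FCMFit} for the in-brain intensities of this
#'   slice.
#' @param inBrainMask logical matrix; \code{sum(inBrainMask)} must equal
#'   the number of fitted points.
#' @param mode "components" (requires C >= 3) or "whole" (C >= 2).
#' @param minSeparation separation factor of the tumor-presence test
#'   (0 disables).
#' @return integer label matrix (0/1/2).
#' @export
assignComponents <- function(sliceImg, fit, inBrainMask,
                             mode = c("components", "whole"),
                             minSeparation = 4) {
  mode <- match.arg(mode)
  stopifnot(is(fit, "FCMFit"))
  C <- length(fit@centroids)
  if (mode == "components" && C < 3L)
    stopValidation("component output requires C >= 3 clusters (got %d); use mode = 'whole'", C)
  if (mode == "whole" && C < 2L)
    stopValidation("whole-tumor mode requires C >= 2 clusters")
  n <- sum(inBrainMask)
  if (n != nrow(fit@memberships))
    stopValidation("in-brain mask has %d voxels but the fit holds %d points",
                   n, nrow(fit@memberships))
  labels <- matrix(0L, nrow(sliceImg), ncol(sliceImg))
  if (n == 0L) return(labels)

  # a usable fit needs a tumor-candidate cluster above at least one
  # other: two non-empty clusters (a slice may hold only edema + brain)
  nonEmpty <- which(!fit@empty)
  if (length(nonEmpty) < 2L) return(labels)  # degenerate slice

  hard <- max.col(fit@memberships, ties.method = "last")
  vals <- sliceImg[inBrainMask]

  # group clusters whose centroid gaps sit at the noise level: FCM may
  # split one tissue mode across clusters (several on the heavy brain
  # mode, or two on edema), so tissue identity belongs to the *group*
  cen <- fit@centroids[nonEmpty]
  bottomRes <- vals[hard == nonEmpty[1]]
  noise <- if (minSeparation > 0 && length(bottomRes) > 1L)
    stats::mad(bottomRes) else 0
  sepGap <- max(minSeparation * noise, 1e-6 * max(abs(vals), 1))
  cut <- diff(cen) > sepGap
  if (!any(cut))
    return(labels)  # one tissue group: nothing stands clear of the noise
  grp <- cumsum(c(0L, cut))
  edemaClusters <- nonEmpty[grp == max(grp)]

  edema <- matrix(FALSE, nrow(sliceImg), ncol(sliceImg))
  edema[inBrainMask] <- hard %in% edemaClusters
  labels[edema] <- 2L
  if (mode == "whole") return(labels)

  necIdx <- max(nonEmpty[grp == max(grp) - 1L])  # top of the next group
  necCand <- matrix(FALSE, nrow(sliceImg), ncol(sliceImg))
  necCand[inBrainMask] <- hard == necIdx
  if (any(edema)) {
    hull <- convexHullFill(edema)
    labels[necCand & hull] <- 1L
  }
  labels
}

#' Slice-wise fuzzy C-means tumor segmentation
#'
#' For each axial slice with enough in-brain (non-zero) voxels: cluster
#' the in-brain intensities, map clusters to tumor components, and
#' clean each label with small-object removal. Slices with fewer
#' in-brain voxels than C are skipped (with a log message when they
#' contain any brain at all). Deterministic for the default
#' initialisation, and for fixed \code{seed} under random
#' initialisation.
#'
#' @param vol single-modality, brain-extracted
#'   \linkS4class{BrainVolume}.
#' @param params an \linkS4class{FCMParams}.
#' @param mode "components" or "whole" (see
#'   \code{\link{assignComponents}}).
#' @return A \linkS4class{TumorMask} with component labels
#'   (\code{undifferentiated = FALSE}).
#' @examples
#' p <- makePhantom(phantomSpec(shape = c(41L, 35L, 9L), spacing = c(1, 1, 4),
#'                              headSemiAxes = c(16, 13, 3.5),
#'                              tumorCenter = c(13, 18, 5),
#'                              coreRadius = 2, edemaRadius = 5))
#' m <- segmentFCM(p$volume, fcmParams(minArea = 0))
#' diceCoefficient(wholeTumor(m), wholeTumor(p$mask))
#' @export
segmentFCM <- function(vol, params = fcmParams(),
                       mode = c("components", "whole")) {
  mode <- match.arg(mode)
  stopifnot(is(vol, "BrainVolume"))
  if (mode == "components" && params@nClusters < 3L)
    stopValidation("component segmentation requires C >= 3")
  if (params@nClusters < 2L)
    stopValidation("segmentation requires C >= 2")
  dims <- dim(vol@data)
  labels <- array(0L, dims)
  for (z in seq_len(dims[3])) {
    slice <- vol@data[, , z]
    inb <- slice != 0
    n <- sum(inb)
    if (n < params@nClusters) {
      if (n > 0L)
        message(sprintf("slice %d skipped: %d in-brain voxel(s) < C = %d",
                        z, n, params@nClusters))
      next
    }
    fit <- fcmCluster(slice[inb], params)
    lab <- assignComponents(slice, fit, inb, mode,
                            minSeparation = params@minSeparation)
    # clean edema first: the necrotic territory is bounded by the hull
    # of the *cleaned* edema, so noise specks cannot inflate it
    edema <- removeSmallObjects(lab == 2L, params@minArea,
                                params@connectivity)
    nec <- lab == 1L
    if (any(nec)) {
      nec <- nec & (if (any(edema)) convexHullFill(edema)
                    else matrix(FALSE, dims[1], dims[2]))
      nec <- removeSmallObjects(nec, params@minArea, params@connectivity)
    }
    lab[] <- 0L
    lab[edema] <- 2L
    lab[nec] <- 1L
    labels[, , z] <- lab
  }
  tumorMask(labels, spacing = vol@spacing, sliceGap = vol@sliceGap)
}
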