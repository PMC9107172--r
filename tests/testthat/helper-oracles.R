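# Independent brute-force oracles, deliberately written as plain loops:
# they must share no code path with the implementations they check.

# Flood fill from a seed over |I - I[seed]| <= tol, queue-based.
bruteFlood <- function(img, seed, tol, connectivity = 8) {
  nx <- nrow(img); ny <- ncol(img)
  nb <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  s <- img[seed[1], seed[2]]
  out <- matrix(FALSE, nx, ny)
  queue <- list(seed)
  out[seed[1], seed[2]] <- TRUE
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (k in seq_len(nrow(nb))) {
      q <- p + nb[k, ]
      if (q[1] < 1 || q[1] > nx || q[2] < 1 || q[2] > ny) next
      if (out[q[1], q[2]]) next
      if (abs(img[q[1], q[2]] - s) <= tol) {
        out[q[1], q[2]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
  }
  out
}

# Component labelling by repeated flood fill over a binary mask.
bruteLabel <- function(mask, connectivity = 8) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  img <- ifelse(mask, 1, 0)
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      comp <- bruteFlood(img, c(i, j), tol = 0.5, connectivity)
      lab[comp & mask] <- nxt
    }
  }
  lab
}

# Boundary voxels by explicit face-neighbour scan (3D).
bruteBoundary3D <- function(mask) {
  d <- dim(mask)
  res <- NULL
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!mask[i, j, k]) next
    onb <- i == 1 || i == d[1] || j == 1 || j == d[2] || k == 1 || k == d[3]
    if (!onb) {
      onb <- !(mask[i - 1, j, k] && mask[i + 1, j, k] &&
               mask[i, j - 1, k] && mask[i, j + 1, k] &&
               mask[i, j, k - 1] && mask[i, j, k + 1])
    } else {
      # at the volume edge an out-of-volume neighbour counts as background
      onb <- TRUE
    }
    if (onb) res <- rbind(res, c(i, j, k))
  }
  res
}

# All-pairs max-min symmetric Hausdorff over boundary voxels.
bruteHausdorff <- function(a, b) {
  A <- bruteBoundary3D(a); B <- bruteBoundary3D(b)
  dmat <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    dmat[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# Direct double-sum evaluation of the fuzzy cost, summed in the
# opposite order (clusters outer, points inner) from the implementation.
bruteFuzzyCost <- function(values, centroids, W, m) {
  J <- 0
  for (i in seq_along(centroids)) {
    if (is.na(centroids[i])) next
    for (j in seq_along(values))
      J <- J + W[j, i]^m * (values[j] - centroids[i])^2
  }
  J
}

flip1 <- function(a) a[rev(seq_len(dim(a)[1])), , , drop = FALSE]

# Small fast phantoms shared across test files: a clinical-flavoured
# anisotropic geometry at desk scale.
smallSpec <- function(...) {
  args <- utils::modifyList(
    list(shape = c(61L, 55L, 12L), spacing = c(1, 1, 4),
         headSemiAxes = c(26, 22, 5), tumorCenter = c(19, 28, 6),
         coreRadius = 4, edemaRadius = 9),
    list(...))
  do.call(phantomSpec, args)
}

tinySpec <- function(...) {
  phantomSpec(shape = c(21L, 19L, 5L), headSemiAxes = c(8, 7, 2),
              laterality = "none", ...)
}

diceOf <- function(mask, gt, component = "whole_tumor") {
  diceCoefficient(componentMask(mask, component),
                  componentMask(gt, component))
}
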