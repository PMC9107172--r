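## Low-level 2D image primitives used by the segmentation pipelines.
## All operate on matrices indexed [x, y] (x = left-right image axis).

#' Label connected components of a binary 2D mask
#'
#' Run-length, union-find two-pass labelling. Components are numbered
#' 1..k in order of their first (column-major) run; background is 0.
#'
#' @param m logical matrix.
#' @param connectivity 4 (faces) or 8 (faces + diagonals).
#' @return integer matrix of component labels.
#' @export
labelComponents2D <- function(m, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L))
    stopValidation("connectivity must be 4 or 8")
  nx <- nrow(m); ny <- ncol(m)
  lab <- matrix(0L, nx, ny)
  if (!any(m)) return(lab)

  run_start <- integer(0); run_end <- integer(0)
  run_col <- integer(0); col_runs <- vector("list", ny)
  nrun <- 0L
  for (y in seq_len(ny)) {
    col <- m[, y]
    if (!any(col)) { col_runs[[y]] <- integer(0); next }
    r <- rle(as.logical(col))
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    keep <- r$values
    s <- s[keep]; e <- e[keep]
    idx <- nrun + seq_along(s)
    run_start <- c(run_start, s); run_end <- c(run_end, e)
    run_col <- c(run_col, rep.int(y, length(s)))
    col_runs[[y]] <- idx
    nrun <- nrun + length(s)
  }

  parent <- seq_len(nrun)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  slack <- if (connectivity == 8L) 1L else 0L
  for (y in seq_len(ny - 1L)) {
    a <- col_runs[[y]]; b <- col_runs[[y + 1L]]
    if (!length(a) || !length(b)) next
    ea <- run_end[a]; sa <- run_start[a]
    # runs within a column are disjoint and sorted, so overlaps with a
    # run in the next column form a contiguous range
    lo <- findInterval(run_start[b] - slack - 1L, ea) + 1L
    hi <- findInterval(run_end[b] + slack, sa)
    for (k in seq_along(b)) {
      if (lo[k] > hi[k]) next
      rj <- findRoot(b[k])
      for (i in lo[k]:hi[k]) {
        ri <- findRoot(a[i])
        if (ri != rj) { parent[ri] <- rj; rj <- findRoot(rj) }
      }
    }
  }

  roots <- vapply(seq_len(nrun), findRoot, integer(1))
  relab <- match(roots, unique(roots))  # numbered by first run occurrence
  for (k in seq_len(nrun))
    lab[run_start[k]:run_end[k], run_col[k]] <- relab[k]
  lab
}

#' Fill enclosed holes of a binary 2D mask
#'
#' Background components not connected to the image border are turned
#' foreground. The background is labelled with the complementary
#' connectivity of the foreground (8 -> 4 and vice versa), the standard
#' digital-topology pairing.
#'
#' @param m logical matrix.
#' @param connectivity foreground connectivity (4 or 8).
#' @return logical matrix with holes filled.
#' @export
fillHoles2D <- function(m, connectivity = 8L) {
  bgconn <- if (connectivity == 8L) 4L else 8L
  lab <- labelComponents2D(!m, bgconn)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border != 0L]
  m | (lab != 0L & !(lab %in% border))
}

## Shift matrix content by (dx, dy), zero-filling exposed edges.
shiftMatrix <- function(m, dx, dy) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(0, nx, ny)
  xs <- max(1L, 1L + dx):min(nx, nx + dx)
  ys <- max(1L, 1L + dy):min(ny, ny + dy)
  if (length(xs) < 1L || length(ys) < 1L) return(out)
  out[xs, ys] <- m[xs - dx, ys - dy]
  out
}

#' Mask-aware in-plane Gaussian smoothing
#'
#' Separable Gaussian convolution restricted to a mask (normalised
#' convolution): values outside the mask neither contribute nor receive,
#' so tissue near the brain edge is not dragged toward the zero
#' background.
#'
#' @param m numeric matrix.
#' @param sigma kernel std dev in voxels; 0 returns the input.
#' @param mask logical matrix of valid pixels (default: m != 0).
#' @return smoothed matrix, zero outside the mask.
#' @export
gaussianBlur2D <- function(m, sigma, mask = NULL) {
  if (sigma <= 0) return(m)
  if (is.null(mask)) mask <- m != 0
  r <- as.integer(ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  conv1 <- function(z, along) {
    out <- matrix(0, nrow(z), ncol(z))
    for (i in seq_along(k)) {
      d <- i - r - 1L
      out <- out + k[i] * (if (along == 1L) shiftMatrix(z, d, 0L)
                           else shiftMatrix(z, 0L, d))
    }
    out
  }
  w <- mask * 1.0
  num <- conv1(conv1(m * w, 1L), 2L)
  den <- conv1(conv1(w, 1L), 2L)
  out <- matrix(0, nrow(m), ncol(m))
  ok <- mask & den > 1e-12
  out[ok] <- num[ok] / den[ok]
  out
}

#' Nearest-neighbour in-plane rotation of a 2D image
#'
#' Rotates content counter-clockwise (in array axes) by \code{deg} about
#' the image center, zero-filling uncovered pixels. Nearest-neighbour
#' resampling keeps intensities and labels exact.
#'
#' @param m numeric or integer matrix.
#' @param deg rotation in degrees; 0 returns the input unchanged.
#' @return matrix of the same shape and storage mode.
#' @export
rotateImageNN <- function(m, deg) {
  if (deg == 0) return(m)
  nx <- nrow(m); ny <- ncol(m)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  th <- deg * pi / 180
  ii <- rep(seq_len(nx), times = ny) - cx
  jj <- rep(seq_len(ny), each = nx) - cy
  si <- round(cos(th) * ii + sin(th) * jj + cx)
  sj <- round(-sin(th) * ii + cos(th) * jj + cy)
  ok <- si >= 1 & si <= nx & sj >= 1 & sj <= ny
  out <- matrix(if (is.integer(m)) 0L else 0, nx, ny)
  out[cbind(rep(seq_len(nx), ny)[ok], rep(seq_len(ny), each = nx)[ok])] <-
    m[cbind(si[ok], sj[ok])]
  out
}

## Rotate every axial slice of a 3D array by the same in-plane angle.
rotateSlices <- function(a, deg) {
  if (deg == 0) return(a)
  for (z in seq_len(dim(a)[3])) a[, , z] <- rotateImageNN(a[, , z], deg)
  a
}

## Reverse a 3D array (or matrix) along the x (first) axis.
flipX <- function(a) {
  if (is.matrix(a)) a[rev(seq_len(nrow(a))), , drop = FALSE]
  else a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
}

#' Filled convex hull of a binary 2D mask
#'
#' Lattice points inside (or on) the convex hull of the foreground
#' pixel coordinates. Used to delimit the tumor territory enclosed by
#' the edema component.
#'
#' @param m logical matrix.
#' @return logical matrix of the filled hull (equals \code{m} when fewer
#'   than 3 foreground pixels exist).
#' @export
convexHullFill <- function(m) {
  pts <- which(m, arr.ind = TRUE)
  if (nrow(pts) < 3L) return(m)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  vx <- pts[h, 1]; vy <- pts[h, 2]
  if (length(unique(vx)) == 1L || length(unique(vy)) == 1L) return(m)
  xr <- range(vx); yr <- range(vy)
  gx <- rep(xr[1]:xr[2], times = yr[2] - yr[1] + 1L)
  gy <- rep(yr[1]:yr[2], each = xr[2] - xr[1] + 1L)
  inside <- rep(TRUE, length(gx))
  nv <- length(vx)
  nxt <- c(seq_len(nv)[-1], 1L)
  # orientation-robust: interior cross products share the sign of the
  # polygon's signed area; tolerance admits boundary points
  sgn <- sign(sum(vx * vy[nxt] - vx[nxt] * vy))
  if (sgn == 0) return(m)
  for (e in seq_len(nv)) {
    x1 <- vx[e]; y1 <- vy[e]
    x2 <- vx[nxt[e]]; y2 <- vy[nxt[e]]
    cr <- (x2 - x1) * (gy - y1) - (y2 - y1) * (gx - x1)
    inside <- inside & sgn * cr >= -1e-9
  }
  out <- matrix(FALSE, nrow(m), ncol(m))
  out[cbind(gx[inside], gy[inside])] <- TRUE
  out | m
}
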