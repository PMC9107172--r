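# Fuzzy C-means solver, component mapping, cleanup and the slice-wise
# segmentation pipeline.

test_that("C = 1 reduces to the arithmetic mean", {
  set.seed(1)
  x <- stats::rnorm(40, 12, 3)
  fit <- fcmCluster(x, fcmParams(C = 1))
  expect_equal(fit@centroids, mean(x))
  expect_true(all(fit@memberships == 1))
  expect_equal(fit@cost, sum((x - mean(x))^2))
})

test_that("two well-separated deltas are recovered as their locations", {
  x <- c(rep(10, 500), rep(90, 500))
  fit <- fcmCluster(x, fcmParams(C = 2))
  expect_equal(fit@centroids, c(10, 90), tolerance = 1e-4)
  near <- fit@memberships[cbind(seq_along(x), ifelse(x == 10, 1L, 2L))]
  expect_true(all(near >= 0.999))
})

test_that("the four-point fit matches an independent cost evaluation", {
  x <- c(1, 2, 9, 10)
  fit <- fcmCluster(x, fcmParams(C = 2, tol = 1e-6))
  expect_equal(fit@centroids, c(1.5, 9.5), tolerance = 0.2 / 1.5)
  expect_lt(abs(fit@cost -
                bruteFuzzyCost(x, fit@centroids, fit@memberships, 2)), 1e-6)
})

test_that("membership rows always sum to one and the cost never increases", {
  set.seed(21)
  for (rep in 1:5) {
    x <- c(stats::rnorm(80, 50, 6), stats::rnorm(30, 110, 9),
           stats::rnorm(15, 170, 5))
    fit <- fcmCluster(x, fcmParams(C = sample(2:4, 1)))
    expect_equal(rowSums(fit@memberships), rep(1, length(x)),
                 tolerance = 1e-9)
    expect_true(all(fit@memberships >= 0 & fit@memberships <= 1))
    expect_true(all(diff(fit@costTrace) <= 1e-9))
    expect_gte(fit@cost, 0)
  }
})

test_that("the solver is permutation invariant and scale equivariant", {
  set.seed(31)
  x <- c(stats::rnorm(60, 20, 2), stats::rnorm(60, 60, 3))
  p <- fcmParams(C = 2)
  fit <- fcmCluster(x, p)
  perm <- sample(seq_along(x))
  fit2 <- fcmCluster(x[perm], p)
  expect_equal(fit2@centroids, fit@centroids, tolerance = 1e-8)
  expect_equal(fit2@memberships, fit@memberships[perm, ], tolerance = 1e-8)
  for (alpha in c(0.25, 3)) {
    fits <- fcmCluster(alpha * x, fcmParams(C = 2, tol = 1e-5 * alpha))
    expect_equal(fits@centroids, alpha * fit@centroids, tolerance = 1e-6)
    expect_equal(fits@memberships, fit@memberships, tolerance = 1e-6)
  }
})

test_that("degenerate and invalid inputs are handled as specified", {
  fit <- fcmCluster(rep(7, 50), fcmParams(C = 3))
  expect_equal(fit@centroids[1], 7)
  expect_true(all(is.na(fit@centroids[2:3])))
  expect_equal(fit@empty, c(FALSE, TRUE, TRUE))
  expect_false(fit@converged)
  expect_error(fcmCluster(c(1, 2), fcmParams(C = 3)), "at least")
  expect_error(fcmCluster(c(1, NA, 3), fcmParams(C = 2)), "finite")
})

test_that("the cost functional evaluates the double sum exactly", {
  expect_equal(fcmCost(5, 5, matrix(1, 1, 1), 2), 0)
  expect_equal(fcmCost(3, 1, matrix(1, 1, 1), 2), 4)
  set.seed(8)
  x <- stats::rnorm(25); ctr <- c(-1, 0.5, 2)
  W <- matrix(stats::runif(75), 25, 3); W <- W / rowSums(W)
  expect_lt(abs(fcmCost(x, ctr, W, 1.7) - bruteFuzzyCost(x, ctr, W, 1.7)),
            1e-12)
  expect_error(fcmCost(x, ctr, W[1:10, ], 2), "matrix")
})

test_that("small-object removal is an area opening", {
  m <- matrix(FALSE, 20, 20)
  m[2:3, 2] <- TRUE; m[2, 3] <- TRUE          # 3-voxel speck
  m[8:17, 8:12] <- TRUE                       # 50-voxel block
  out <- removeSmallObjects(m, 10, 8L)
  expect_equal(sum(out), 50)
  expect_true(all(out[8:17, 8:12]))
  expect_identical(removeSmallObjects(m, 0, 8L), m)
  expect_identical(removeSmallObjects(matrix(FALSE, 4, 4), 5),
                   matrix(FALSE, 4, 4))
  # idempotence and monotonicity in minArea
  expect_identical(removeSmallObjects(out, 10, 8L), out)
  set.seed(5)
  r <- matrix(stats::runif(400) < 0.35, 20, 20)
  prev <- r
  for (a in c(2, 5, 10, 20)) {
    cur <- removeSmallObjects(r, a, 8L)
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("cluster-to-component mapping recovers a four-tissue slice exactly", {
  sl <- matrix(0.1, 30, 30)
  sl[6:25, 6:25] <- 0.4
  sl[10:21, 10:21] <- 0.9   # edema block
  sl[14:17, 14:17] <- 0.6   # necrotic interior
  inb <- matrix(TRUE, 30, 30)
  fit <- fcmCluster(sl[inb], fcmParams(C = 4))
  lab <- assignComponents(sl, fit, inb)
  expect_identical(lab == 2L, sl == 0.9)
  expect_identical(lab == 1L, sl == 0.6)

  # whole-tumor-only mode with two clusters
  sl2 <- matrix(0.2, 20, 20); sl2[5:12, 6:13] <- 0.9
  fit2 <- fcmCluster(sl2[sl2 > 0], fcmParams(C = 2))
  lab2 <- assignComponents(sl2, fit2, sl2 > 0, mode = "whole")
  expect_identical(lab2 == 2L, sl2 == 0.9)
  expect_error(assignComponents(sl2, fit2, sl2 > 0), "C >= 3")
})

test_that("a slice without tumor-grade separation stays unlabelled", {
  set.seed(12)
  sl <- matrix(stats::rnorm(900, 100, 8), 30, 30)  # single tissue + noise
  inb <- matrix(TRUE, 30, 30)
  fit <- fcmCluster(sl[inb], fcmParams(C = 4))
  lab <- assignComponents(sl, fit, inb)
  expect_equal(sum(lab), 0)
})

test_that("slice-wise segmentation is deterministic and exact when noise-free", {
  p <- makePhantom(smallSpec())
  m1 <- segmentFCM(p$volume, fcmParams(minArea = 0, seed = 1))
  m2 <- segmentFCM(p$volume, fcmParams(minArea = 0, seed = 999))
  expect_identical(maskLabels(m1), maskLabels(m2))
  expect_identical(maskLabels(m1), maskLabels(p$mask))
  expect_false(m1@undifferentiated)
})

test_that("a tumor-free noisy brain stays essentially unlabelled", {
  p <- makePhantom(phantomSpec(shape = c(61L, 55L, 12L), spacing = c(1, 1, 4),
                               headSemiAxes = c(26, 22, 5),
                               laterality = "none", noiseSigma = 8,
                               seed = 3))
  m <- segmentFCM(p$volume)
  frac <- sum(maskLabels(m) > 0) / sum(imgData(p$volume) != 0)
  expect_lt(frac, 0.01)
})
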