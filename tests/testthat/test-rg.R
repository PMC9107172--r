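# Contrast stretching, seeding, region growing, and the full pipeline.

test_that("contrast stretch maps the percentile window linearly onto [0,1]", {
  sl <- matrix(0, 12, 12)
  sl[2:11, 2:11] <- seq(1, 100)
  st <- contrastStretch(sl, rgParams(stretchPercentiles = c(1, 99)))
  expect_equal(min(st[sl != 0]), 0)   # low tail clipped to 0
  expect_equal(max(st), 1)            # high tail clipped to 1
  expect_true(all(st >= 0 & st <= 1))
  # interior of the window is exactly linear
  q <- stats::quantile(1:100, c(0.01, 0.99), names = FALSE)
  mid <- sl > q[1] & sl < q[2]
  expect_equal(st[mid], (sl[mid] - q[1]) / (q[2] - q[1]))
})

test_that("contrast stretch is monotone and handles constant slices", {
  set.seed(9)
  sl <- matrix(stats::rexp(400) + 0.1, 20, 20)
  st <- contrastStretch(sl)
  o <- order(sl)
  expect_true(all(diff(st[o]) >= -1e-12))
  expect_warning(out <- contrastStretch(matrix(5, 8, 8)), "constant")
  expect_true(all(out == 0))
})

test_that("seed selection takes the brightest candidate, ties lexicographic", {
  img <- matrix(0, 10, 10)
  cand <- matrix(TRUE, 10, 10)
  img[5, 7] <- 3
  expect_equal(selectSeed(img, cand), c(5L, 7L))
  img[2, 9] <- 5; img[3, 1] <- 5
  expect_equal(selectSeed(img, cand), c(2L, 9L))
  expect_null(selectSeed(img, matrix(FALSE, 10, 10)))
})

test_that("region growing matches brute-force flood fill", {
  img <- matrix(0.1, 9, 9)
  img[3:7, 3:7] <- 0.9
  # tolerance below the contrast: exactly the square
  g <- regionGrow(img, c(5, 5), rgParams(intensityTolerance = 0.2))
  expect_equal(sum(g), 25)
  expect_identical(g, bruteFlood(img, c(5, 5), 0.2))
  # tolerance above the contrast: floods the whole image
  g2 <- regionGrow(img, c(5, 5), rgParams(intensityTolerance = 0.9))
  expect_true(all(g2))
  # seeding the background grows the background only
  g3 <- regionGrow(img, c(1, 1), rgParams(intensityTolerance = 0.05))
  expect_identical(g3, bruteFlood(img, c(1, 1), 0.05))
  expect_equal(sum(g3 & img > 0.5), 0)
  expect_error(regionGrow(img, c(0, 5), rgParams()), "outside")
})

test_that("grown regions are single connected components containing the seed", {
  set.seed(4)
  for (rep in 1:10) {
    img <- matrix(stats::runif(14 * 14), 14, 14)
    seed <- c(sample(14, 1), sample(14, 1))
    for (conn in c(4L, 8L)) {
      g <- regionGrow(img, seed, rgParams(intensityTolerance = 0.3,
                                          connectivity = conn))
      expect_true(g[seed[1], seed[2]])
      expect_equal(max(bruteLabel(g, conn)), 1)
      expect_identical(g, bruteFlood(img, seed, 0.3, conn))
    }
  }
})

test_that("the full pipeline recovers a unilateral tumor on noisy data", {
  p <- makePhantom(smallSpec(noiseSigma = 8, seed = 7))
  seg <- segmentRG(p$volume)
  expect_gte(diceOf(tumorMaskOf(seg), p$mask), 0.9)
  expect_equal(seg@tumorSide, "left")
  expect_false(seg@bilateralSuspect)
  # RG cannot resolve components: label 1 never appears
  expect_equal(sum(maskLabels(tumorMaskOf(seg)) == 1L), 0)
  expect_true(tumorMaskOf(seg)@undifferentiated)
})

test_that("a tumor-free symmetric brain yields an empty mask", {
  p <- makePhantom(phantomSpec(shape = c(41L, 35L, 7L),
                               headSemiAxes = c(16, 13, 3),
                               laterality = "none"))
  w <- capture_warnings(seg <- segmentRG(p$volume))
  expect_match(w, "empty mask", all = FALSE)
  expect_equal(sum(wholeTumor(tumorMaskOf(seg))), 0)
})

test_that("mirrored bilateral tumors raise the bilateral-suspect flag", {
  p <- makePhantom(smallSpec(laterality = "bilateral_mirrored"))
  w <- capture_warnings(seg <- segmentRG(p$volume))
  expect_match(w, "bilateral-suspect", all = FALSE)
  expect_true(seg@bilateralSuspect)
  expect_lt(seg@confidence, 0.65)
})

test_that("flipping the volume flips the mask and swaps the side", {
  pl <- makePhantom(phantomSpec())
  pr <- makePhantom(phantomSpec(laterality = "right"))
  sl <- suppressWarnings(segmentRG(pl$volume))
  sr <- suppressWarnings(segmentRG(pr$volume))
  expect_equal(sl@tumorSide, "left")
  expect_equal(sr@tumorSide, "right")
  expect_identical(maskLabels(tumorMaskOf(sr)), flip1(maskLabels(tumorMaskOf(sl))))
})
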