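# Synthetic phantom generator.

test_that("construction is deterministic and labels drive intensities", {
  sp <- smallSpec(noiseSigma = 5, biasAmplitude = 0.1, seed = 17)
  p1 <- makePhantom(sp)
  p2 <- makePhantom(sp)
  expect_identical(imgData(p1$volume), imgData(p2$volume))
  expect_identical(maskLabels(p1$mask), maskLabels(p2$mask))

  # zero-noise, zero-bias: intensity is a deterministic function of label
  clean <- makePhantom(smallSpec())
  dat <- imgData(clean$volume); lab <- maskLabels(clean$mask)
  expect_true(all(dat[lab == 2L] == 200))
  expect_true(all(dat[lab == 1L] == 160))
  inBrainOnly <- dat != 0 & lab == 0L
  expect_true(all(dat[inBrainOnly] == 120))
  expect_true(all(dat[dat == 0] == 0))
})

test_that("left and right phantoms are exact mirror images", {
  pl <- makePhantom(smallSpec())
  pr <- makePhantom(smallSpec(laterality = "right"))
  expect_identical(imgData(pr$volume), flip1(imgData(pl$volume)))
  expect_identical(maskLabels(pr$mask), flip1(maskLabels(pl$mask)))
  # bilateral = union of the left tumor and its mirror
  pb <- makePhantom(smallSpec(laterality = "bilateral_mirrored"))
  lab <- maskLabels(pb$mask)
  expect_identical(lab, flip1(lab))
  expect_equal(sum(lab >= 1L), 2 * sum(maskLabels(pl$mask) >= 1L))
})

test_that("noise has the requested scale inside the brain", {
  sp <- phantomSpec(noiseSigma = 10, seed = 23)   # default 101x91x24 head
  noisy <- makePhantom(sp)
  spClean <- sp; spClean@noiseSigma <- 0
  clean <- makePhantom(spClean)
  brain <- imgData(clean$volume) != 0
  resid <- imgData(noisy$volume)[brain] - imgData(clean$volume)[brain]
  expect_lt(abs(stats::sd(resid) - 10) / 10, 0.05)
  # background remains exactly zero, as after skull stripping
  expect_true(all(imgData(noisy$volume)[!brain] == 0))
})

test_that("ground-truth volume matches an independent ellipsoid count", {
  sp <- smallSpec()
  p <- makePhantom(sp)
  # voxel enumeration oracle for the edema ellipsoid
  ctr <- sp@tumorCenter
  rz <- max(1, sp@edemaRadius * sp@spacing[1] /
              (sp@spacing[3] + sp@sliceGap))
  cnt <- 0
  for (k in seq_len(sp@shape[3])) for (j in seq_len(sp@shape[2]))
    for (i in seq_len(sp@shape[1]))
      if (((i - ctr[1]) / sp@edemaRadius)^2 +
          ((j - ctr[2]) / sp@edemaRadius)^2 +
          ((k - ctr[3]) / rz)^2 <= 1) cnt <- cnt + 1
  expect_equal(sum(wholeTumor(p$mask)), cnt)
})

test_that("bias field is smooth, multiplicative and bounded", {
  sp <- smallSpec(biasAmplitude = 0.2)
  p <- makePhantom(sp)
  clean <- makePhantom(smallSpec())
  ratio <- imgData(p$volume) / imgData(clean$volume)
  ratio <- ratio[imgData(clean$volume) != 0]
  expect_true(all(ratio >= 0.8 - 1e-9 & ratio <= 1.2 + 1e-9))
  expect_gt(stats::sd(ratio), 0.01)   # actually varies across the head
})

test_that("invalid specifications are refused", {
  expect_error(makePhantom(smallSpec(coreRadius = 10)), "edemaRadius")
  expect_error(makePhantom(smallSpec(tumorCenter = c(3, 3, 6))),
               "protrudes")
  expect_error(
    makePhantom(phantomSpec(tissueIntensities = c(background = 0,
                                                  brain = 200,
                                                  necrotic = 160,
                                                  edema = 100))),
    "background < brain")
})

test_that("clinical preset encodes the non-contiguous slice geometry", {
  p <- makeClinicalPhantom(laterality = "none")
  expect_equal(dim(imgData(p$volume)), c(256, 224, 20))
  expect_equal(voxelSpacing(p$volume), c(0.5, 0.5, 5))
  expect_equal(sliceGap(p$volume), 1.5)
  # isotropic override
  iso <- makeClinicalPhantom(laterality = "none", spacing = c(1, 1, 1),
                             sliceGap = 0, shape = c(64L, 56L, 20L),
                             headSemiAxes = c(26, 22, 8))
  expect_equal(sliceGap(iso$volume), 0)
  # a single-slice phantom is accepted
  one <- makeClinicalPhantom(laterality = "none", shape = c(64L, 56L, 1L),
                             headSemiAxes = c(26, 22, 40))
  expect_equal(dim(imgData(one$volume))[3], 1)
})

test_that("the canonical suite holds the six named scenarios", {
  suite <- phantomSuite(1)
  expect_setequal(names(suite),
                  c("symmetric_clean", "unilateral_LGG_like",
                    "unilateral_HGG_like", "bilateral_mirrored",
                    "rotated_7deg", "noisy_biased"))
  expect_equal(sum(maskLabels(suite$symmetric_clean$mask)), 0)
  expect_gt(sum(maskLabels(suite$unilateral_HGG_like$mask) == 1L),
            sum(maskLabels(suite$unilateral_LGG_like$mask) == 1L))
  lab <- maskLabels(suite$bilateral_mirrored$mask)
  expect_identical(lab, flip1(lab))
  expect_equal(suite$rotated_7deg$spec@rotationDeg, 7)
})
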