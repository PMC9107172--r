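# Dice, boundary Hausdorff and volume, plus reporting.

test_that("Dice identities and conventions hold", {
  a <- array(FALSE, c(6, 6, 3)); a[2:4, 2:4, 1:2] <- TRUE
  b <- array(FALSE, c(6, 6, 3)); b[5:6, 5:6, 3] <- TRUE
  expect_equal(diceCoefficient(a, a), 1)
  expect_equal(diceCoefficient(a, b), 0)          # disjoint
  expect_equal(diceCoefficient(array(FALSE, c(3, 3, 3)),
                               array(FALSE, c(3, 3, 3))), 1)
  expect_equal(diceCoefficient(a, array(FALSE, c(6, 6, 3))), 0)
  # |A| = 4, |B| = 2, |A n B| = 2 -> 2*2/6
  x <- array(FALSE, c(4, 4, 1)); x[1:4, 1, 1] <- TRUE
  y <- array(FALSE, c(4, 4, 1)); y[1:2, 1, 1] <- TRUE
  expect_equal(diceCoefficient(x, y), 2 / 3)
  expect_equal(diceCoefficient(x, y), diceCoefficient(y, x))
  expect_error(diceCoefficient(a, array(FALSE, c(6, 6, 4))), "shape")
})

test_that("boundary voxels are the face-adjacent shell", {
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  expect_equal(unname(boundaryVoxels(one)), matrix(c(3, 3, 3), 1))
  cube <- array(FALSE, c(7, 7, 7)); cube[3:5, 3:5, 3:5] <- TRUE
  bv <- boundaryVoxels(cube)
  expect_equal(nrow(bv), 26)                       # all but the center
  expect_false(any(bv[, 1] == 4 & bv[, 2] == 4 & bv[, 3] == 4))
  expect_equal(nrow(boundaryVoxels(array(FALSE, c(4, 4, 4)))), 0)
  # brute-force agreement on random masks
  set.seed(19)
  for (rep in 1:5) {
    m <- array(stats::runif(6^3) < 0.4, c(6, 6, 6))
    if (!any(m)) next
    got <- boundaryVoxels(m)
    ref <- bruteBoundary3D(m)
    expect_equal(got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE],
                 unname(ref[order(ref[, 1], ref[, 2], ref[, 3]), ,
                            drop = FALSE]),
                 ignore_attr = TRUE)
  }
})

test_that("Hausdorff distance matches hand values and the brute-force oracle", {
  a <- array(FALSE, c(5, 6, 3)); a[1, 1, 1] <- TRUE
  b <- array(FALSE, c(5, 6, 3)); b[4, 5, 1] <- TRUE
  expect_equal(hausdorffDistance(a, b), 5)        # 3-4-5 triangle
  expect_equal(hausdorffDistance(a, a), 0)
  expect_equal(hausdorffDistance(a, b), hausdorffDistance(b, a))
  expect_error(hausdorffDistance(a, array(FALSE, c(5, 6, 3))), "undefined")

  set.seed(77)
  for (rep in 1:30) {
    m1 <- array(stats::runif(8^3) < 0.12, c(8, 8, 8))
    m2 <- array(stats::runif(8^3) < 0.12, c(8, 8, 8))
    if (!any(m1) || !any(m2)) next
    expect_equal(hausdorffDistance(m1, m2), bruteHausdorff(m1, m2))
  }
})

test_that("mm Hausdorff uses the effective slice spacing", {
  a <- array(FALSE, c(4, 4, 4)); a[2, 2, 2] <- TRUE
  b <- array(FALSE, c(4, 4, 4)); b[2, 2, 3] <- TRUE
  expect_equal(hausdorffDistance(a, b), 1)
  # 5 mm slices with a 1.5 mm gap: centers are 6.5 mm apart
  expect_equal(hausdorffDistance(a, b, spacing = c(0.5, 0.5, 5),
                                 sliceGap = 1.5), 6.5)
})

test_that("volumes count voxels; mm3 excludes the slice gap", {
  block <- array(FALSE, c(12, 12, 5)); block[1:10, 1:10, 1:3] <- TRUE
  v <- maskVolume(block)
  expect_equal(v$voxels, 300)
  expect_true(is.na(v$mm3))
  v2 <- maskVolume(block, spacing = c(0.5, 0.5, 5), sliceGap = 1.5)
  expect_equal(v2$mm3, 375)                      # 300 * 1.25
  expect_true(v2$gapCaveat)
  expect_equal(maskVolume(array(FALSE, c(3, 3, 3)))$voxels, 0)
})

test_that("metrics are translation invariant and monotone under dilation", {
  base <- array(FALSE, c(10, 10, 6)); base[3:5, 3:5, 2:3] <- TRUE
  shft <- array(FALSE, c(10, 10, 6)); shft[5:7, 6:8, 4:5] <- TRUE
  other <- array(FALSE, c(10, 10, 6)); other[4:5, 3:4, 2] <- TRUE
  otherS <- array(FALSE, c(10, 10, 6)); otherS[6:7, 6:7, 4] <- TRUE
  expect_equal(diceCoefficient(base, other), diceCoefficient(shft, otherS))
  expect_equal(hausdorffDistance(base, other), hausdorffDistance(shft, otherS))

  # dilating the prediction away from the truth cannot shrink Hausdorff
  dil <- base
  dil[2:6, 2:6, 1:4] <- TRUE
  expect_gte(hausdorffDistance(dil, base), hausdorffDistance(base, base))
  expect_lte(hausdorffDistance(dil, base), sqrt(3) * 2)
})

test_that("evaluation reports all components and flags what is absent", {
  p <- makePhantom(smallSpec())
  rep1 <- evaluateSegmentation(p$mask, p$mask)
  expect_equal(rep1$dsc, rep(1, 3))
  expect_equal(rep1$hausdorff_voxels, rep(0, 3))
  expect_equal(rep1$vol_pred_voxels, rep1$vol_gt_voxels)
  expect_equal(rep1$component, c("whole_tumor", "edema", "necrotic"))

  # region-growing style prediction: whole tumor only, components dashed
  rgStyle <- tumorMask(ifelse(maskLabels(p$mask) >= 1L, 2L, 0L),
                       voxelSpacing(p$mask), sliceGap(p$mask),
                       undifferentiated = TRUE)
  rep2 <- evaluateSegmentation(rgStyle, p$mask)
  expect_equal(rep2$dsc[rep2$component == "whole_tumor"], 1)
  np <- rep2[rep2$component != "whole_tumor", ]
  expect_true(all(np$flags == "not_produced"))
  expect_true(all(is.na(np$dsc)))

  bad <- tumorMask(array(0L, c(5, 5, 5)))
  expect_error(evaluateSegmentation(bad, p$mask), "compatible")
})

test_that("a one-voxel dilation keeps Hausdorff within one diagonal step", {
  gt <- array(FALSE, c(12, 12, 8)); gt[4:8, 4:8, 3:5] <- TRUE
  dil <- array(FALSE, c(12, 12, 8)); dil[3:9, 3:9, 2:6] <- TRUE
  expect_lte(hausdorffDistance(dil, gt), sqrt(3))
})

test_that("batch reports aggregate per component with exclusions counted", {
  p <- makePhantom(smallSpec())
  sp <- voxelSpacing(p$mask); gp <- sliceGap(p$mask)
  good <- p$mask
  half <- maskLabels(p$mask)
  half[, , seq(1, dim(half)[3], by = 2)] <- 0L
  halfM <- tumorMask(half, sp, gp)
  emptyM <- tumorMask(array(0L, dim(half)), sp, gp)

  tab <- batchReport(list(list(pred = good, gt = p$mask, case = "a"),
                          list(pred = halfM, gt = p$mask, case = "b"),
                          list(pred = emptyM, gt = p$mask, case = "c")))
  wt <- tab[tab$component == "whole_tumor", ]
  expect_equal(wt$dsc[wt$case == "mean"],
               mean(wt$dsc[wt$case != "mean"]))
  expect_equal(wt$n_hausdorff_excluded[wt$case == "mean"], 1)
  # Hausdorff mean is over the defined cases only
  expect_equal(wt$hausdorff_voxels[wt$case == "mean"],
               mean(wt$hausdorff_voxels[wt$case %in% c("a", "b")]))

  single <- batchReport(list(list(pred = good, gt = p$mask)))
  expect_equal(single$dsc[single$case == "mean"],
               single$dsc[single$case != "mean"])
  expect_error(batchReport(list()), "at least one")
})
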