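# Clinical quantitation: liver CV, lesion segmentation, equivalent diameter,
# normalization and stratification.

test_that("liver CV: hand-computed values, scale invariance, containment", {
  # four-voxel toy VOI {4,4,8,8} SUV: mean 6, population SD 2, CV 33.33%
  g <- VoxelGrid(2L, 2L, 1L, 10, 10, 10)
  v <- ActivityVolume(array(c(4, 4, 8, 8), c(2, 2, 1)), g, suvScale = 1)
  lc <- liverCv(v, voiCenter = c(0, 0, 0), voiDiameter = 25)
  expect_equal(lc$nVoxels, 4)
  expect_equal(lc$suvMean, 6)
  expect_equal(lc$suvSd, 2)
  expect_equal(lc$cv, 100 / 3, tolerance = 1e-9)
  # constant VOI -> CV 0
  vc <- ActivityVolume(array(5, c(2, 2, 1)), g, suvScale = 1)
  expect_equal(liverCv(vc, voiCenter = c(0, 0, 0), voiDiameter = 25)$cv, 0)
  # scaling the image leaves CV unchanged
  v2 <- ActivityVolume(voxelData(v) * 3.7, g, suvScale = 1)
  expect_equal(liverCv(v2, voiCenter = c(0, 0, 0), voiDiameter = 25)$cv,
               lc$cv, tolerance = 1e-12)
  # VOI outside the liver compartment errors
  p <- smallPatientSpec()
  vol <- buildPatient(p, smallPatientGrid())
  expect_error(liverCv(vol, voiCenter = p@liverCenter + c(50, 0, 0),
                       patient = p),
               "outside the liver")
})

test_that("normalized CV maps reference to 1 and divides through", {
  ncv <- normalizedCv(c(O3 = 12.88, O2 = 14.36))
  expect_identical(ncv[["O3"]], 1.0)
  expect_equal(ncv[["O2"]], 1.115, tolerance = 1e-3)
  expect_error(normalizedCv(c(O2 = 14.36)), "missing")
})

test_that("equivalent diameter inverts the sphere volume exactly", {
  expect_equal(equivalentDiameter(pi / 6 * 1000), 10)
  expect_equal(equivalentDiameter(1000), 12.407, tolerance = 1e-4)
  expect_equal(equivalentDiameter(0), 0)
  expect_error(equivalentDiameter(-1), ">= 0")
  # exact inverse round-trip
  for (d in c(0.5, 7.7, 14, 27.3))
    expect_equal(equivalentDiameter(pi / 6 * d^3), d, tolerance = 1e-12)
})

test_that("lesion segmentation recovers a known sphere on a fine grid", {
  # 14 mm sphere at 8:1 contrast, noise-free, 1.75 mm voxels
  g <- VoxelGrid(48L, 48L, 24L, 1.75, 1.75, 1.75)
  spec <- PatientSpec(bodySemiAxes = c(41, 41),
                      liverCenter = c(15, 15, 0),
                      liverSemiAxes = c(18, 18, 14),
                      lesions = list(LesionSpec(c(-15, -15, 0), 14, 8)),
                      voiDiameter = 10)
  vol <- buildPatient(spec, g)
  seg <- segmentLesion(vol, c(-15, -15, 0))
  expect_equal(seg$suvMax, 8, tolerance = 1e-6)
  # equivalent diameter within one voxel of the true 14 mm
  expect_equal(seg$equivalentDiameter, 14, tolerance = 1.75 / 14)
})

test_that("segmentation limit cases and degenerate seeds", {
  g <- VoxelGrid(24L, 24L, 8L, 3, 3, 3)
  vals <- array(1, c(24, 24, 8))
  vals[12, 12, 4] <- 10
  vals[13, 12, 4] <- 6
  v <- ActivityVolume(vals, g, suvScale = 1)
  # threshold 1.0: exactly the max voxel
  s1 <- segmentLesion(v, c(0, 0, 0), thresholdFraction = 1.0)
  expect_equal(s1$nVoxels, 1)
  # threshold 0.41: the connected pair above 4.1
  s2 <- segmentLesion(v, c(0, 0, 0), thresholdFraction = 0.41)
  expect_equal(s2$nVoxels, 2)
  expect_true(all(c(10, 6) >= s2$threshold))
  # flat background -> degenerate-lesion error
  flat <- ActivityVolume(array(2, c(24, 24, 8)), g, suvScale = 1)
  expect_error(segmentLesion(flat, c(0, 0, 0)), "degenerate")
})

test_that("segmentation output is connected and above threshold", {
  set.seed(5)
  g <- VoxelGrid(32L, 32L, 12L, 3, 3, 3)
  base <- array(1 + 0.05 * runif(32 * 32 * 12), c(32, 32, 12))
  co <- (seq_len(32) - 16.5) * 3
  cz <- (seq_len(12) - 6.5) * 3
  for (i in 1:32) for (k in 1:12) {
    d2 <- co[i]^2 + co^2 + cz[k]^2
    base[i, d2 <= 81, k] <- 8  # 18 mm sphere
  }
  v <- ActivityVolume(base, g, suvScale = 1)
  seg <- segmentLesion(v, c(0, 0, 0))
  expect_gte(min(voxelData(v)[seg$maxIndex] / 1), seg$threshold / 8)
  expect_equal(seg$suvMax, 8)
  # every segmented voxel >= 0.41 * SUVmax by construction: volume matches
  # the voxel count times voxel volume
  expect_equal(seg$volumeMm3, seg$nVoxels * 27)
})

test_that("per-lesion SUVmax normalization uses mean-of-ratios", {
  m <- rbind(c(2, 4), c(10, 10))
  dimnames(m) <- list(c("l1", "l2"), c("O3", "HR3.2"))
  ns <- normalizedSuvmax(m, reference = "O3")
  expect_equal(unname(ns$ratios[, "HR3.2"]), c(2, 1))
  expect_equal(ns$summary$mean[ns$summary$group == "HR3.2"], 1.5)
  # demonstrates mean-of-ratios != ratio-of-means (14/12)
  expect_false(isTRUE(all.equal(1.5, 14 / 12)))
  # reference group: all ratios 1, SD 0
  expect_equal(unname(ns$ratios[, "O3"]), c(1, 1))
  expect_equal(ns$summary$sd[ns$summary$group == "O3"], 0)
  m2 <- rbind(c(10.28, 12.58))
  dimnames(m2) <- list("l", c("O3", "HR3.03"))
  expect_equal(unname(normalizedSuvmax(m2)$ratios[, "HR3.03"]), 1.224,
               tolerance = 1e-3)
  expect_error(normalizedSuvmax(m2, reference = "O2"), "missing")
})

test_that("stratification boundaries are half-open as declared", {
  expect_equal(stratify(9.9)$sizeClass, "small")
  expect_equal(stratify(10.0)$sizeClass, "medium")
  expect_equal(stratify(19.9)$sizeClass, "medium")
  expect_equal(stratify(20.0)$sizeClass, "large")
  expect_equal(stratify(27.3)$sizeClass, "large")
  expect_equal(stratify(iaPerKg = 1.59)$iaClass, "low")
  expect_equal(stratify(iaPerKg = 1.60)$iaClass, "high")
  expect_equal(stratify(bmi = 23.99)$bmiClass, "normal_or_under")
  expect_equal(stratify(bmi = 24.0)$bmiClass, "overweight")
})
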