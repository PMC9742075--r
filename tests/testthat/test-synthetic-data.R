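# Phantom and patient generators: compartment values, ratios, SUV round-trip.

test_that("binary-mode phantom reproduces the 4:1 fill ratio exactly", {
  spec <- NemaPhantomSpec()
  expect_equal(spec@backgroundConcentration, 3.3)   # 13.2 / 4
  vol <- buildNemaPhantom(spec, VoxelGrid(), boundary = "binary")
  v <- voxelData(vol)
  sphereVox <- v[v > spec@backgroundConcentration]
  bgVox <- v[v > 0 & v <= spec@backgroundConcentration]
  expect_equal(unique(sphereVox), spec@sphereConcentration)
  expect_equal(unique(bgVox), spec@backgroundConcentration)
  expect_equal(mean(sphereVox) / mean(bgVox), 4.0)
})

test_that("subsampled phantom keeps the interior ratio within 1%", {
  spec <- smallPhantomSpec()
  vol <- buildNemaPhantom(spec, smallPhantomGrid(), boundary = "subsample")
  v <- voxelData(vol)
  # interior voxels only: strictly at the two fill levels
  sphereMean <- mean(v[abs(v - spec@sphereConcentration) < 1e-9])
  bgMean <- mean(v[abs(v - spec@backgroundConcentration) < 1e-9])
  expect_equal(sphereMean / bgMean, 4.0, tolerance = 0.01)
  # boundary voxels are proper mixtures
  mix <- v[v > spec@backgroundConcentration + 1e-9 &
             v < spec@sphereConcentration - 1e-9]
  expect_gt(length(mix), 0)
  expect_true(all(v >= 0))
})

test_that("zero-concentration phantom yields an all-zero volume", {
  spec <- NemaPhantomSpec(sphereConcentration = 0,
                          backgroundConcentration = 0)
  vol <- buildNemaPhantom(spec, smallPhantomGrid(), boundary = "binary")
  expect_true(all(voxelData(vol) == 0))
})

test_that("phantom geometry violations error", {
  expect_error(NemaPhantomSpec(sphereCenters = cbind(c(0, 4), c(0, 0)),
                               sphereDiameters = c(10, 13)),
               "overlap")
  expect_error(NemaPhantomSpec(sphereCenters = cbind(200, 0),
                               sphereDiameters = 10),
               "outside the body")
})

test_that("patient SUV calibration and round-trip", {
  p <- PatientSpec()   # 97.2 MBq, 61.3 kg
  expect_equal(suvScaleOf(p), 97200 / 61300)
  expect_equal(suvScaleOf(p), 1.586, tolerance = 1e-3)
  grid <- smallPatientGrid()
  vol <- buildPatient(smallPatientSpec(), grid, boundary = "binary")
  # liver voxel concentration = liverSuv * suvScale, and suvOf inverts it
  liverConc <- 5.96 * suvScale(vol)
  expect_equal(liverConc, 9.45, tolerance = 1e-2)
  expect_equal(suvOf(vol, liverConc), 5.96)
  expect_equal(suvOf(vol, 0), 0)
  expect_equal(suvOf(vol, suvScale(vol)), 1.0)
  # all three compartments present at their assigned SUVs
  suv <- as.numeric(voxelData(vol)) / suvScale(vol)
  expect_equal(sort(unique(suv)), c(0, 1, 5.96, 10))
})

test_that("patient generator is deterministic and supports zero lesions", {
  grid <- smallPatientGrid()
  s <- smallPatientSpec(lesions = list())
  v1 <- buildPatient(s, grid)
  v2 <- buildPatient(s, grid)
  expect_identical(voxelData(v1), voxelData(v2))
  suv <- voxelData(v1) / suvScale(v1)
  expect_lte(max(suv), s@liverSuv + 1e-9)  # only liver + background
})

test_that("lesion placement violations error", {
  grid <- smallPatientGrid()
  # lesion inside the liver VOI placement region
  badVoi <- smallPatientSpec(lesions = list(LesionSpec(c(50, 10, 0), 10, 10)))
  expect_error(buildPatient(badVoi, grid), "VOI placement")
  badBody <- smallPatientSpec(lesions = list(LesionSpec(c(-135, 0, 0), 20, 10)))
  expect_error(buildPatient(badBody, grid), "outside the body")
})
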