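# Projector/adjoint pair, PSF blur, Poisson acquisition.

test_that("project and backproject are exact adjoints (vs explicit matrix)", {
  g <- tinyGrid(); geom <- tinyGeom()
  set.seed(1)
  # inner-product identity on random vectors
  for (i in 1:5) {
    x <- ActivityVolume(array(runif(64), c(8, 8, 1)), g)
    y <- array(runif(geom@nBins * geom@nAngles), c(geom@nBins, geom@nAngles, 1))
    lhs <- sum(sinoData(project(x, geom)) * y)
    rhs <- sum(voxelData(x) * voxelData(backproject(Sinogram(y, geom), g)))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)
  }
  # the internal sparse matrix agrees with a column-by-column materialization
  Aexp <- explicitSystemMatrix(g, geom)
  A <- as.matrix(systemMatrix(g, geom))
  expect_equal(A, Aexp, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("projection is linear and conserves activity across angles", {
  g <- smallPhantomGrid(); geom <- smallPhantomGeom()
  vol <- buildNemaPhantom(smallPhantomSpec(), g)
  s1 <- sinoData(project(vol, geom))
  s2 <- sinoData(project(ActivityVolume(voxelData(vol) * 2, g), geom))
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
  # per-angle bin sums constant within 0.5% (support well inside the FOV)
  perAngle <- apply(s1, 2, sum)
  expect_lt((max(perAngle) - min(perAngle)) / mean(perAngle), 0.005)
  # and equal to total activity times voxel area / bin width
  expected <- sum(voxelData(vol)) * g@dx * g@dy / geom@binWidth
  expect_equal(mean(perAngle), expected, tolerance = 0.005)
  # zero volume -> zero sinogram
  z <- project(ActivityVolume(array(0, c(g@nx, g@ny, 1)), g), geom)
  expect_true(all(sinoData(z) == 0))
})

test_that("backprojection: zero input, sensitivity positivity, shape checks", {
  g <- tinyGrid(); geom <- tinyGeom()
  z <- backproject(Sinogram(array(0, c(geom@nBins, geom@nAngles, 1)), geom), g)
  expect_true(all(voxelData(z) == 0))
  ones <- Sinogram(array(1, c(geom@nBins, geom@nAngles, 1)), geom)
  sens <- voxelData(backproject(ones, g))
  expect_true(all(sens > 0))  # every voxel of the small grid is in the FOV
  # geometry that cannot cover the grid errors
  tooSmall <- new("ProjectionGeometry", nAngles = 8L, nBins = 5L, binWidth = 3)
  expect_error(project(ActivityVolume(array(1, c(8, 8, 1)), g), tooSmall),
               "cover")
})

test_that("Gaussian blur: identity at 0, conservation, measured FWHM", {
  g <- VoxelGrid(65L, 65L, 1L, 1, 1, 1)   # fine 1 mm grid for the profile
  delta <- array(0, c(65, 65, 1)); delta[33, 33, 1] <- 1
  vol <- ActivityVolume(delta, g)
  expect_identical(applyPsf(vol, 0), vol)
  b <- applyPsf(vol, 3)
  expect_lt(max(voxelData(b)), 1)
  expect_equal(sum(voxelData(b)), 1, tolerance = 1e-6)
  # measured FWHM of the central profile within half a voxel of 3 mm
  prof <- voxelData(b)[, 33, 1]
  half <- max(prof) / 2
  above <- which(prof >= half)
  lo <- min(above); hi <- max(above)
  # linear interpolation at the half-maximum crossings
  fL <- lo - 1 + (prof[lo - 1] - half) / (prof[lo - 1] - prof[lo])
  fR <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  expect_equal((fR - fL) * g@dx, 3, tolerance = 0.5 / 3)
  expect_error(applyPsf(vol, -1), ">= 0")
})

test_that("blur conserves totals on realistic volumes", {
  g <- smallPhantomGrid()
  vol <- buildNemaPhantom(smallPhantomSpec(), g)
  b <- applyPsf(vol, 4)
  expect_equal(sum(voxelData(b)), sum(voxelData(vol)), tolerance = 1e-6)
})

test_that("Poisson acquisition: determinism, budget ratios, totals", {
  g <- smallPhantomGrid(); geom <- smallPhantomGeom()
  expected <- project(buildNemaPhantom(smallPhantomSpec(), g), geom)
  b <- CountBudget(2, 1e6, seed = 99L)
  c1 <- poissonAcquire(expected, b)
  c2 <- poissonAcquire(expected, b)
  expect_identical(sinoData(c1), sinoData(c2))
  expect_identical(sinoKind(c1), "counts")
  # total counts within 3 sqrt(B) of B
  expect_lt(abs(sum(sinoData(c1)) - 1e6), 3 * sqrt(1e6))
  # duration-class budget ratios are exact
  expect_equal(phantomBudget(3)@expectedTotalCounts /
                 phantomBudget(2)@expectedTotalCounts, 46 / 31)
  expect_equal(patientBudget(3)@expectedTotalCounts /
                 patientBudget(2)@expectedTotalCounts, 3 / 2)
  # zero expected + positive budget errors; zero budget passes through
  zeroSino <- Sinogram(array(0, dim(sinoData(expected))), geom)
  expect_error(poissonAcquire(zeroSino, b), "all-zero")
  z <- poissonAcquire(zeroSino, CountBudget(2, 0, 1L))
  expect_true(all(sinoData(z) == 0))
})

test_that("acquisition does not disturb the global RNG stream", {
  g <- smallPhantomGrid(); geom <- smallPhantomGeom()
  expected <- project(buildNemaPhantom(smallPhantomSpec(), g), geom)
  set.seed(123); r1 <- runif(1)
  set.seed(123)
  invisible(poissonAcquire(expected, CountBudget(2, 1e5, 7L)))
  r2 <- runif(1)
  expect_identical(r1, r2)
})
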