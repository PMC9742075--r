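# OSEM / penalized-EM reconstruction: conservation, reduction, monotonicity,
# labels.

test_that("MLEM (subsets = 1) conserves counts after every full iteration", {
  g <- smallPhantomGrid(); geom <- smallPhantomGeom()
  truth <- buildNemaPhantom(smallPhantomSpec(), g)
  counts <- simulateData(truth, geom, CountBudget(2, 2e5, 3L), psfFwhm = 4)
  totalCounts <- sum(sinoData(counts))
  for (iters in c(1L, 3L)) {
    rec <- osemReconstruct(counts,
                           OsemProtocol(iterations = iters, subsets = 1L,
                                        postFilterFwhm = 0),
                           g, geom)
    # sensitivity-weighted image total equals total counts:
    # sum_j s_j x_j = sum_i y_i  (x in count-density units: undo countScale)
    A <- systemMatrix(g, geom)
    blur <- PETsimIQ:::.blurOperator(g, 4)
    s <- as.numeric(blur$bw(matrix(as.numeric(Matrix::t(A) %*%
                                                rep(1, nrow(A))), g@nx * g@ny, 1)))
    x <- as.numeric(voxelData(reconImage(rec))) * counts@meta$countScale
    expect_equal(sum(s * x), totalCounts, tolerance = 1e-6)
  }
})

test_that("noiseless MLEM error decreases with iterations and recovers the 22 mm sphere", {
  g <- smallPhantomGrid(); geom <- smallPhantomGeom()
  spec <- smallPhantomSpec()
  truth <- buildNemaPhantom(spec, g)
  expected <- project(applyPsf(truth, 4), geom)
  # noiseless "counts": expected values on a fine integer scale
  noiseless <- Sinogram(round(sinoData(expected) * 1e4), geom,
                        kind = "counts")
  rmse <- c()
  xs <- list()
  for (iters in c(5L, 20L, 80L, 200L)) {
    rec <- osemReconstruct(noiseless,
                           OsemProtocol(iterations = iters, subsets = 1L,
                                        postFilterFwhm = 0), g, geom)
    x <- voxelData(reconImage(rec)) / 1e4
    rmse <- c(rmse, sqrt(mean((x - voxelData(truth))^2)))
    xs[[length(xs) + 1]] <- x
  }
  expect_true(all(diff(rmse) < 0))
  # 22 mm sphere mean within 5% of truth after 200 iterations
  m <- PETsimIQ:::.sphereMask(g, c(spec@sphereCenters[4, ], 0),
                              spec@sphereDiameters[4] / 2 - g@dx)  # interior
  expect_equal(mean(xs[[4]][m]), spec@sphereConcentration, tolerance = 0.05)
})

test_that("beta = 0 penalized EM is bit-identical to unfiltered OSEM", {
  g <- smallPhantomGrid(); geom <- smallPhantomGeom()
  truth <- buildNemaPhantom(smallPhantomSpec(), g)
  counts <- simulateData(truth, geom, CountBudget(2, 3e5, 9L), psfFwhm = 4)
  o <- osemReconstruct(counts,
                       OsemProtocol(iterations = 4L, postFilterFwhm = 0),
                       g, geom)
  p <- pemReconstruct(counts,
                      PemProtocol(beta = 0, iterations = 4L, stopTol = 0),
                      g, geom)
  expect_identical(voxelData(reconImage(o)), voxelData(reconImage(p)))
})

test_that("reconstructions are nonnegative, deterministic, zero data give zero image", {
  g <- smallPhantomGrid(); geom <- smallPhantomGeom()
  truth <- buildNemaPhantom(smallPhantomSpec(), g)
  counts <- simulateData(truth, geom, CountBudget(2, 3e5, 10L), psfFwhm = 4)
  p1 <- pemReconstruct(counts, PemProtocol(beta = 0.3), g, geom)
  p2 <- pemReconstruct(counts, PemProtocol(beta = 0.3), g, geom)
  expect_identical(voxelData(reconImage(p1)), voxelData(reconImage(p2)))
  expect_gte(min(voxelData(reconImage(p1))), 0)
  zero <- Sinogram(array(0, dim(sinoData(counts))), geom, kind = "counts")
  z <- osemReconstruct(zero, OsemProtocol(), g, geom)
  expect_true(all(voxelData(reconImage(z)) == 0))
})

test_that("total variation of the reconstruction is non-increasing in beta", {
  g <- smallPhantomGrid(); geom <- smallPhantomGeom()
  truth <- buildNemaPhantom(smallPhantomSpec(), g)
  counts <- simulateData(truth, geom, CountBudget(2, 5e5, 21L), psfFwhm = 4)
  tv <- function(x) {
    v <- voxelData(reconImage(x))
    sum(abs(diff(v[, , 1]))) + sum(abs(t(diff(t(v[, , 1])))))
  }
  tvs <- vapply(c(0.03, 0.07, 0.1, 0.2, 0.3, 0.4, 0.5), function(b)
    tv(pemReconstruct(counts, PemProtocol(beta = b), g, geom)), numeric(1))
  viol <- sum(diff(tvs) > 0)
  expect_lte(viol / length(diff(tvs)), 0.01)
})

test_that("subset/angle incompatibility errors", {
  g <- smallPhantomGrid(); geom <- smallPhantomGeom()  # 40 angles
  truth <- buildNemaPhantom(smallPhantomSpec(), g)
  counts <- simulateData(truth, geom, CountBudget(2, 1e5, 2L), psfFwhm = 0)
  expect_error(osemReconstruct(counts, OsemProtocol(subsets = 7L), g, geom),
               "divide")
})

test_that("group labels format and round-trip the full arm set", {
  expect_equal(makeGroupLabel("OSEM", 3)@label, "O3")
  expect_equal(makeGroupLabel("OSEM", 2)@label, "O2")
  expect_equal(makeGroupLabel("PEM", 2, 0.03)@label, "HR2.03")
  expect_equal(makeGroupLabel("PEM", 3, 0.5)@label, "HR3.5")
  expect_error(makeGroupLabel("FBP", 2), "unknown algorithm")
  expect_error(makeGroupLabel("PEM", 2), "need beta")
  for (d in c(2, 3)) for (b in c(0.03, 0.07, 0.1, 0.2, 0.3, 0.4, 0.5)) {
    lbl <- makeGroupLabel("PEM", d, b)
    back <- parseGroupLabel(lbl@label)
    expect_equal(back@beta, b)
    expect_equal(back@durationClass, d)
  }
  expect_equal(parseGroupLabel("O2")@algorithm, "OSEM")
  expect_error(parseGroupLabel("Q3"), "unrecognized")
})
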