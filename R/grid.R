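# Constructors, accessors and show methods for the core value classes.

#' Construct a VoxelGrid
#'
#' @param nx,ny,nz voxel counts (default 192 x 192 x 1: the clinical in-plane
#'   grid with a single slice, the phantom default).
#' @param dx,dy in-plane voxel size in mm (default 3.12).
#' @param dz slice thickness in mm (default 2.68).
#' @return a [VoxelGrid-class] object.
#' @examples
#' g <- VoxelGrid()                      # 192 x 192 x 1 at 3.12/2.68 mm
#' gp <- VoxelGrid(nz = 20L)             # patient-style slab
#' @export
VoxelGrid <- function(nx = 192L, ny = 192L, nz = 1L,
                      dx = 3.12, dy = 3.12, dz = 2.68) {
  new("VoxelGrid", nx = as.integer(nx), ny = as.integer(ny),
      nz = as.integer(nz), dx = dx, dy = dy, dz = dz)
}

# voxel-center coordinates (mm, origin at grid center) along one axis
.axisCoords <- function(n, d) (seq_len(n) - (n + 1) / 2) * d

.gridCoords <- function(grid) {
  list(x = .axisCoords(grid@nx, grid@dx),
       y = .axisCoords(grid@ny, grid@dy),
       z = .axisCoords(grid@nz, grid@dz))
}

.voxelVolume <- function(grid) grid@dx * grid@dy * grid@dz

#' Construct an ActivityVolume
#'
#' @param values nx x ny x nz numeric array of activity concentrations
#'   (kBq/mL).
#' @param grid a [VoxelGrid-class].
#' @param suvScale kBq/mL per SUV unit (default 1).
#' @return an [ActivityVolume-class] object.
#' @export
ActivityVolume <- function(values, grid, suvScale = 1) {
  new("ActivityVolume", values = values, grid = grid, suvScale = suvScale)
}

#' Construct a ProjectionGeometry
#'
#' @param nAngles angles over 180 degrees (default 60; divisible by the
#'   default 20 subsets).
#' @param nBins radial bins; if `NULL`, derived from `grid` to cover its
#'   diagonal.
#' @param binWidth radial bin width in mm (default: the in-plane voxel size of
#'   `grid`, or 3.12).
#' @param grid optional [VoxelGrid-class] used to derive `nBins`/`binWidth`.
#' @return a [ProjectionGeometry-class] object.
#' @export
ProjectionGeometry <- function(nAngles = 60L, nBins = NULL, binWidth = NULL,
                               grid = NULL) {
  if (is.null(binWidth))
    binWidth <- if (is.null(grid)) 3.12 else min(grid@dx, grid@dy)
  if (is.null(nBins)) {
    if (is.null(grid))
      stop("either nBins or grid must be given")
    diag <- sqrt((grid@nx * grid@dx)^2 + (grid@ny * grid@dy)^2)
    nBins <- ceiling(diag / binWidth) + 1L
  }
  if (nBins %% 2L == 0L) nBins <- nBins + 1L  # odd: center bin on the axis
  new("ProjectionGeometry", nAngles = as.integer(nAngles),
      nBins = as.integer(nBins), binWidth = binWidth)
}

#' Construct a CountBudget
#'
#' @param durationClass 2 or 3 (minutes-per-bed equivalent).
#' @param expectedTotalCounts expected total counts of the acquisition.
#' @param seed integer RNG seed for the Poisson draw.
#' @return a [CountBudget-class] object.
#' @export
CountBudget <- function(durationClass, expectedTotalCounts, seed = 1L) {
  new("CountBudget", durationClass = durationClass,
      expectedTotalCounts = expectedTotalCounts, seed = as.integer(seed))
}

#' Construct a Sinogram
#'
#' @param values nBins x nAngles x nz array.
#' @param geometry a [ProjectionGeometry-class].
#' @param kind `"expected"` or `"counts"`.
#' @param meta list of provenance metadata.
#' @return a [Sinogram-class] object.
#' @export
Sinogram <- function(values, geometry, kind = "expected", meta = list()) {
  new("Sinogram", values = values, geometry = geometry, kind = kind,
      meta = meta)
}

#' Construct reconstruction protocols
#'
#' `OsemProtocol()` describes standard OSEM (default: 2 iterations, 20
#' subsets, 3 mm Gaussian post-filter). `PemProtocol()` describes the
#' one-step-late TV-penalized EM arm for one penalization factor `beta`
#' (default schedule 2 iterations x 20 subsets matching the OSEM protocol,
#' no post-filter).
#'
#' @param iterations,subsets iteration schedule.
#' @param postFilterFwhm OSEM Gaussian post-filter FWHM, mm.
#' @param modelPsfFwhm Gaussian resolution-model FWHM, mm (shared between the
#'   simulation and the reconstruction forward model).
#' @return a protocol object.
#' @export
OsemProtocol <- function(iterations = 2L, subsets = 20L, postFilterFwhm = 3,
                         modelPsfFwhm = 4) {
  new("OsemProtocol", iterations = as.integer(iterations),
      subsets = as.integer(subsets), postFilterFwhm = postFilterFwhm,
      modelPsfFwhm = modelPsfFwhm)
}

#' @rdname OsemProtocol
#' @param beta penalization factor (conventional grid: 0.03, 0.07, 0.1, 0.2,
#'   0.3, 0.4, 0.5).
#' @param tvEpsilonRel TV smoothing constant relative to the mean nonzero
#'   initialization value.
#' @param kappa global penalty-scale constant (calibrated once, then frozen).
#' @param necReferenceCounts reference count level for the count-dependent
#'   penalty scaling.
#' @param sensitivityWeighting use the normalized local sensitivity weight.
#' @param stopTol relative L2 image-change stopping tolerance.
#' @export
PemProtocol <- function(beta, iterations = 2L, subsets = 20L,
                        tvEpsilonRel = 1e-3, kappa = 0.8,
                        necReferenceCounts = 4.8e6,
                        sensitivityWeighting = TRUE, stopTol = 1e-4,
                        modelPsfFwhm = 4) {
  new("PemProtocol", beta = beta, iterations = as.integer(iterations),
      subsets = as.integer(subsets), tvEpsilonRel = tvEpsilonRel,
      kappa = kappa, necReferenceCounts = necReferenceCounts,
      sensitivityWeighting = sensitivityWeighting, stopTol = stopTol,
      modelPsfFwhm = modelPsfFwhm)
}

#' Accessors for the core classes
#'
#' `voxelData`/`voxelGrid`/`suvScale` read an [ActivityVolume-class];
#' `sinoData`/`sinoGeometry`/`sinoKind` read a [Sinogram-class];
#' `reconImage`/`reconTrace`/`groupLabel` read a [ReconResult-class].
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("voxelData", "ActivityVolume", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("voxelGrid", "ActivityVolume", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("suvScale", "ActivityVolume", function(x) x@suvScale)

#' @rdname accessors
#' @export
setMethod("sinoData", "Sinogram", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("sinoGeometry", "Sinogram", function(x) x@geometry)

#' @rdname accessors
#' @export
setMethod("sinoKind", "Sinogram", function(x) x@kind)

#' @rdname accessors
#' @export
setMethod("reconImage", "ReconResult", function(x) x@image)

#' @rdname accessors
#' @export
setMethod("reconTrace", "ReconResult", function(x) x@trace)

#' @rdname accessors
#' @export
setMethod("groupLabel", "ReconResult", function(x) x@label)

#' Convert a voxel value to SUV
#'
#' SUV convention used everywhere in the package:
#' SUV = concentration / suvScale with suvScale = injected activity \[kBq\]
#' per gram of body weight.
#'
#' @param volume an [ActivityVolume-class] (supplies `suvScale`).
#' @param voxelValue concentration value(s) in kBq/mL.
#' @return SUV value(s).
#' @examples
#' v <- ActivityVolume(array(1.586, c(2, 2, 1)), VoxelGrid(2L, 2L, 1L),
#'                     suvScale = 1.586)
#' suvOf(v, 1.586)  # 1
#' @export
suvOf <- function(volume, voxelValue) {
  stopifnot(is(volume, "ActivityVolume"), volume@suvScale > 0)
  voxelValue / volume@suvScale
}

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              object@nx, object@ny, object@nz,
              object@dx, object@dy, object@dz))
})

setMethod("show", "ActivityVolume", function(object) {
  v <- object@values
  cat(sprintf("ActivityVolume: %d x %d x %d, range [%.4g, %.4g] kBq/mL, suvScale %.4g\n",
              dim(v)[1], dim(v)[2], dim(v)[3], min(v), max(v),
              object@suvScale))
})

setMethod("show", "Sinogram", function(object) {
  d <- dim(object@values)
  cat(sprintf("Sinogram (%s): %d bins x %d angles x %d slices, total %.4g\n",
              object@kind, d[1], d[2], d[3], sum(object@values)))
})

setMethod("show", "ReconResult", function(object) {
  lbl <- if (is.na(object@label@label)) "<unlabelled>" else object@label@label
  cat(sprintf("ReconResult %s: %d iterations, final rel. change %.3g\n",
              lbl, length(object@trace),
              if (length(object@trace)) tail(object@trace, 1) else NA_real_))
  show(object@image)
})

setMethod("show", "GroupLabel", function(object) {
  cat(sprintf("GroupLabel: %s (%s, %g m/b%s)\n", object@label,
              object@algorithm, object@durationClass,
              if (is.na(object@beta)) "" else sprintf(", beta %g", object@beta)))
})
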