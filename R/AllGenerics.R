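# Generics for the core operations and accessors.

#' Forward-project an activity volume to a sinogram
#'
#' Computes, slice by slice, the mm-weighted line integral of the volume along
#' every (angle, bin) ray of a 2D parallel-beam geometry. Linear in the input;
#' the exact adjoint is [backproject()].
#'
#' @param volume an [ActivityVolume].
#' @param geometry a [ProjectionGeometry] whose radial extent covers the grid.
#' @param ... unused.
#' @return a [Sinogram] of kind `"expected"`.
#' @export
setGeneric("project", function(volume, geometry, ...) standardGeneric("project"))

#' Backproject a sinogram onto a voxel grid
#'
#' Exact adjoint of [project()] under the Euclidean inner products: the
#' transpose of the same sparse system matrix.
#'
#' @param sino a [Sinogram].
#' @param grid the target [VoxelGrid].
#' @param ... unused.
#' @return an [ActivityVolume]-shaped image (suvScale 1).
#' @export
setGeneric("backproject", function(sino, grid, ...) standardGeneric("backproject"))

#' Apply an isotropic Gaussian resolution blur
#'
#' In-plane Gaussian convolution with the stated FWHM, using reflected edges so
#' the total is conserved; `fwhm = 0` is the exact identity. For volumes the
#' blur acts in the transaxial plane (the per-slice forward model); for
#' sinograms it acts along the radial bins of each view.
#'
#' @param x an [ActivityVolume] or [Sinogram].
#' @param fwhm numeric FWHM in mm (>= 0).
#' @param ... unused.
#' @return an object of the same class as `x`.
#' @export
setGeneric("applyPsf", function(x, fwhm, ...) standardGeneric("applyPsf"))

#' Draw a Poisson count sinogram at a count budget
#'
#' Rescales an expected sinogram so its total equals the budget's expected
#' total counts, then draws independent Poisson counts per element with the
#' budget's seed (deterministic for a fixed seed).
#'
#' @param expected a [Sinogram] of kind `"expected"`.
#' @param budget a [CountBudget].
#' @param ... unused.
#' @return a [Sinogram] of kind `"counts"`.
#' @export
setGeneric("poissonAcquire",
           function(expected, budget, ...) standardGeneric("poissonAcquire"))

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname accessors
#' @export
setGeneric("voxelGrid", function(x) standardGeneric("voxelGrid"))

#' @rdname accessors
#' @export
setGeneric("suvScale", function(x) standardGeneric("suvScale"))

#' @rdname accessors
#' @export
setGeneric("sinoData", function(x) standardGeneric("sinoData"))

#' @rdname accessors
#' @export
setGeneric("sinoGeometry", function(x) standardGeneric("sinoGeometry"))

#' @rdname accessors
#' @export
setGeneric("sinoKind", function(x) standardGeneric("sinoKind"))

#' @rdname accessors
#' @export
setGeneric("reconImage", function(x) standardGeneric("reconImage"))

#' @rdname accessors
#' @export
setGeneric("reconTrace", function(x) standardGeneric("reconTrace"))

#' @rdname accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))
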