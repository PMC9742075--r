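# Digital NEMA image-quality phantom generation.

#' Construct a NEMA image-quality phantom specification
#'
#' Defaults reproduce the standard hot-sphere fill: the four smallest spheres
#' (10, 13, 17, 22 mm diameter) at 13.2 kBq/mL against a background at one
#' quarter of that concentration (4:1), coplanar on the central slice, centers
#' on the usual 57.2 mm ring inside an elliptical torso outline.
#'
#' @param sphereDiameters sphere diameters, mm.
#' @param sphereConcentration hot-sphere concentration, kBq/mL.
#' @param backgroundConcentration background concentration, kBq/mL (default
#'   sphere/4).
#' @param bodySemiAxes in-plane body ellipse semi-axes, mm.
#' @param sphereCenters n x 2 matrix of in-plane sphere centers (mm); default:
#'   equally spaced on a 57.2 mm radius ring.
#' @return a [PhantomSpec-class] object.
#' @examples
#' spec <- NemaPhantomSpec()
#' spec@sphereConcentration / spec@backgroundConcentration  # 4
#' @export
NemaPhantomSpec <- function(sphereDiameters = c(10, 13, 17, 22),
                            sphereConcentration = 13.2,
                            backgroundConcentration = sphereConcentration / 4,
                            bodySemiAxes = c(150, 110),
                            sphereCenters = NULL) {
  n <- length(sphereDiameters)
  if (is.null(sphereCenters)) {
    ang <- (seq_len(n) - 1) * 2 * pi / 6   # hexagonal positions, 60 deg apart
    sphereCenters <- cbind(57.2 * cos(ang), 57.2 * sin(ang))
  }
  new("PhantomSpec", sphereDiameters = sphereDiameters,
      sphereConcentration = sphereConcentration,
      backgroundConcentration = backgroundConcentration,
      bodySemiAxes = bodySemiAxes, sphereCenters = sphereCenters)
}

# --- sub-voxel occupancy fractions ------------------------------------------
# Occupancy of a compartment per voxel, either by voxel-center membership
# ("binary") or by 3x3x3 center subsampling ("subsample"): the voxel is cut
# into 27 subcells and the fraction of subcell centers inside the compartment
# is the voxel's occupancy. Computation is restricted to the compartment's
# bounding box.

.subOffsets <- function(d, mode) {
  if (mode == "binary") 0 else (c(-1, 0, 1) / 3) * d
}

# fraction array for a sphere (cx, cy, cz mm, radius mm)
.sphereFraction <- function(grid, center, radius, mode) {
  co <- .gridCoords(grid)
  f <- array(0, c(grid@nx, grid@ny, grid@nz))
  ix <- which(abs(co$x - center[1]) <= radius + grid@dx)
  iy <- which(abs(co$y - center[2]) <= radius + grid@dy)
  iz <- which(abs(co$z - center[3]) <= radius + grid@dz)
  if (!length(ix) || !length(iy) || !length(iz)) return(f)
  acc <- array(0, c(length(ix), length(iy), length(iz)))
  ox <- .subOffsets(grid@dx, mode); oy <- .subOffsets(grid@dy, mode)
  oz <- .subOffsets(grid@dz, mode)
  for (ax in ox) for (ay in oy) for (az in oz) {
    dx2 <- (co$x[ix] + ax - center[1])^2
    dy2 <- (co$y[iy] + ay - center[2])^2
    dz2 <- (co$z[iz] + az - center[3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= radius^2
    acc <- acc + inside
  }
  f[ix, iy, iz] <- acc / (length(ox) * length(oy) * length(oz))
  f
}

# fraction array for an axis-aligned ellipsoid
.ellipsoidFraction <- function(grid, center, semiAxes, mode) {
  co <- .gridCoords(grid)
  f <- array(0, c(grid@nx, grid@ny, grid@nz))
  ix <- which(abs(co$x - center[1]) <= semiAxes[1] + grid@dx)
  iy <- which(abs(co$y - center[2]) <= semiAxes[2] + grid@dy)
  iz <- which(abs(co$z - center[3]) <= semiAxes[3] + grid@dz)
  if (!length(ix) || !length(iy) || !length(iz)) return(f)
  acc <- array(0, c(length(ix), length(iy), length(iz)))
  ox <- .subOffsets(grid@dx, mode); oy <- .subOffsets(grid@dy, mode)
  oz <- .subOffsets(grid@dz, mode)
  for (ax in ox) for (ay in oy) for (az in oz) {
    dx2 <- ((co$x[ix] + ax - center[1]) / semiAxes[1])^2
    dy2 <- ((co$y[iy] + ay - center[2]) / semiAxes[2])^2
    dz2 <- ((co$z[iz] + az - center[3]) / semiAxes[3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
    acc <- acc + inside
  }
  f[ix, iy, iz] <- acc / (length(ox) * length(oy) * length(oz))
  f
}

# fraction array for an in-plane ellipse extruded along z (the body outline)
.ellipseFraction <- function(grid, semiAxes, mode) {
  co <- .gridCoords(grid)
  ox <- .subOffsets(grid@dx, mode); oy <- .subOffsets(grid@dy, mode)
  acc <- matrix(0, grid@nx, grid@ny)
  for (ax in ox) for (ay in oy) {
    dx2 <- ((co$x + ax) / semiAxes[1])^2
    dy2 <- ((co$y + ay) / semiAxes[2])^2
    acc <- acc + (outer(dx2, dy2, "+") <= 1)
  }
  array(acc / (length(ox) * length(oy)), c(grid@nx, grid@ny, grid@nz))
}

#' Build the digital NEMA phantom volume
#'
#' Voxels inside a hot sphere carry the sphere concentration, voxels inside
#' the body but outside all spheres carry the background concentration, voxels
#' outside the body carry 0. In `"subsample"` mode (the default) each
#' boundary voxel carries the sub-voxel volume-weighted mixture estimated by
#' 3x3x3 center subsampling, which avoids staircase bias in contrast recovery
#' at these sphere sizes; `"binary"` mode assigns by voxel-center membership
#' and makes compartment means exact.
#'
#' @param spec a [PhantomSpec-class].
#' @param grid a [VoxelGrid-class]; the spheres sit on the central slice.
#' @param boundary `"subsample"` or `"binary"`.
#' @return an [ActivityVolume-class] (suvScale 1; the phantom has no SUV
#'   calibration).
#' @examples
#' vol <- buildNemaPhantom(NemaPhantomSpec(), VoxelGrid(), boundary = "binary")
#' @export
buildNemaPhantom <- function(spec, grid, boundary = c("subsample", "binary")) {
  boundary <- match.arg(boundary)
  validObject(spec); validObject(grid)
  body <- .ellipseFraction(grid, spec@bodySemiAxes, boundary)
  vals <- body * spec@backgroundConcentration
  zc <- 0  # spheres coplanar on the central-slice plane
  for (j in seq_along(spec@sphereDiameters)) {
    fj <- .sphereFraction(grid, c(spec@sphereCenters[j, ], zc),
                          spec@sphereDiameters[j] / 2, boundary)
    vals <- vals + fj * (spec@sphereConcentration -
                           spec@backgroundConcentration)
  }
  ActivityVolume(vals, grid, suvScale = 1)
}

# logical mask of voxel centers inside each compartment (used by evaluation)
.sphereMask <- function(grid, center, radius) {
  .sphereFraction(grid, center, radius, "binary") > 0.5
}

.ellipsoidMask <- function(grid, center, semiAxes) {
  .ellipsoidFraction(grid, center, semiAxes, "binary") > 0.5
}
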