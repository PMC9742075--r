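# Sparse-matrix parallel-beam projector and its exact adjoint.
#
# Per-slice 2D parallel beam, ray-driven with bilinear (Joseph-style)
# interpolation: each ray is sampled at steps of the in-plane voxel size and
# each sample spreads onto the four surrounding pixels, weighted by the step
# length in mm. The whole operator is materialized once per (grid, geometry)
# as a sparse matrix, so the adjoint is its literal transpose.

.projCache <- new.env(parent = emptyenv())

.projKey <- function(grid, geom) {
  sprintf("%d:%d:%g:%g|%d:%d:%g", grid@nx, grid@ny, grid@dx, grid@dy,
          geom@nAngles, geom@nBins, geom@binWidth)
}

.checkCoverage <- function(grid, geom) {
  diag <- sqrt((grid@nx * grid@dx)^2 + (grid@ny * grid@dy)^2)
  if (geom@nBins * geom@binWidth < diag - 1e-9)
    stop("projection geometry too small: radial extent does not cover the grid diagonal")
}

.buildSystemMatrix <- function(grid, geom) {
  nx <- grid@nx; ny <- grid@ny; dx <- grid@dx; dy <- grid@dy
  nA <- geom@nAngles; nB <- geom@nBins; bw <- geom@binWidth
  ang <- (seq_len(nA) - 1) * pi / nA
  s <- (seq_len(nB) - (nB + 1) / 2) * bw
  dt <- min(dx, dy)
  halfDiag <- sqrt((nx * dx)^2 + (ny * dy)^2) / 2
  tt <- seq(-halfDiag - dt, halfDiag + dt, by = dt)
  nt <- length(tt)
  sv <- rep(s, times = nt)
  tv <- rep(tt, each = nB)
  binv <- rep(seq_len(nB), times = nt)

  ii <- vector("list", nA); jj <- vector("list", nA); xx <- vector("list", nA)
  for (a in seq_len(nA)) {
    ca <- cos(ang[a]); sa <- sin(ang[a])
    # detector axis u = (ca, sa); ray direction v = (-sa, ca)
    px <- sv * ca - tv * sa
    py <- sv * sa + tv * ca
    fx <- px / dx + (nx + 1) / 2
    fy <- py / dy + (ny + 1) / 2
    ix <- floor(fx); iy <- floor(fy)
    wx <- fx - ix; wy <- fy - iy
    keep <- ix >= 0L & ix <= nx & iy >= 0L & iy <= ny
    ix <- ix[keep]; iy <- iy[keep]; wx <- wx[keep]; wy <- wy[keep]
    bn <- binv[keep]
    cornX <- c(ix, ix + 1, ix, ix + 1)
    cornY <- c(iy, iy, iy + 1, iy + 1)
    w <- c((1 - wx) * (1 - wy), wx * (1 - wy), (1 - wx) * wy, wx * wy) * dt
    bn4 <- rep.int(bn, 4)
    ok <- cornX >= 1 & cornX <= nx & cornY >= 1 & cornY <= ny & w > 0
    ii[[a]] <- (a - 1L) * nB + bn4[ok]
    jj[[a]] <- (cornY[ok] - 1) * nx + cornX[ok]
    xx[[a]] <- w[ok]
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(nA * nB, nx * ny))
}

# cached system matrix plus subset split (rows grouped by angle stride)
.systemOperator <- function(grid, geom, subsets = 1L) {
  .checkCoverage(grid, geom)
  key <- .projKey(grid, geom)
  entry <- .projCache[[key]]
  if (is.null(entry)) {
    A <- .buildSystemMatrix(grid, geom)
    entry <- list(A = A, At = Matrix::t(A), splits = list())
    .projCache[[key]] <- entry
  }
  skey <- as.character(subsets)
  if (is.null(entry$splits[[skey]])) {
    nA <- geom@nAngles; nB <- geom@nBins
    if (nA %% subsets != 0L)
      stop(sprintf("subsets (%d) must divide the number of angles (%d)",
                   subsets, nA))
    rows <- lapply(seq_len(subsets) - 1L, function(k) {
      angs <- which((seq_len(nA) - 1L) %% subsets == k)
      as.vector(outer(seq_len(nB), (angs - 1L) * nB, "+"))
    })
    Asub <- lapply(rows, function(r) entry$A[r, , drop = FALSE])
    Atsub <- lapply(Asub, Matrix::t)
    entry$splits[[skey]] <- list(rows = rows, Asub = Asub, Atsub = Atsub)
    .projCache[[key]] <- entry
  }
  list(A = entry$A, At = entry$At, split = entry$splits[[skey]])
}

#' Explicitly materialized system matrix
#'
#' Returns the sparse (nAngles x nBins) x (nx x ny) single-slice projection
#' matrix, mainly for verification against the operator form.
#'
#' @param grid a [VoxelGrid-class].
#' @param geometry a [ProjectionGeometry-class].
#' @return a `dgCMatrix` with rays in rows (bin fastest) and pixels in columns
#'   (x fastest).
#' @export
systemMatrix <- function(grid, geometry) {
  .systemOperator(grid, geometry)$A
}

#' @rdname project
#' @export
setMethod("project", signature("ActivityVolume", "ProjectionGeometry"),
  function(volume, geometry, ...) {
    g <- volume@grid
    op <- .systemOperator(g, geometry)
    X <- matrix(volume@values, g@nx * g@ny, g@nz)
    Y <- as.matrix(op$A %*% X)
    Sinogram(array(Y, c(geometry@nBins, geometry@nAngles, g@nz)), geometry,
             kind = "expected")
  })

#' @rdname backproject
#' @export
setMethod("backproject", signature("Sinogram", "VoxelGrid"),
  function(sino, grid, ...) {
    geom <- sino@geometry
    op <- .systemOperator(grid, geom)
    nz <- dim(sino@values)[3]
    Y <- matrix(sino@values, geom@nBins * geom@nAngles, nz)
    X <- as.matrix(op$At %*% Y)
    ActivityVolume(array(pmax(X, 0), c(grid@nx, grid@ny, nz)), grid,
                   suvScale = 1)
  })
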