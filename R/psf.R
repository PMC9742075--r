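# Gaussian resolution model / post-filter, as explicit sparse 1D convolution
# matrices with reflected edges. Materializing the operator keeps its adjoint
# exact (the transpose), which the EM count-conservation identity relies on.

.convCache <- new.env(parent = emptyenv())

.gaussKernel1d <- function(fwhm, spacing) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(4 * sigma / spacing))
  x <- (-r):r
  # integrate the Gaussian over each sample cell for an accurate discrete kernel
  k <- pnorm((x + 0.5) * spacing, sd = sigma) -
       pnorm((x - 0.5) * spacing, sd = sigma)
  k / sum(k)
}

# n x n sparse convolution matrix, symmetric (reflected-edge) boundary
.convMatrix1d <- function(n, fwhm, spacing) {
  key <- sprintf("%d:%g:%g", n, fwhm, spacing)
  G <- .convCache[[key]]
  if (!is.null(G)) return(G)
  k <- .gaussKernel1d(fwhm, spacing)
  r <- (length(k) - 1L) %/% 2L
  if (2L * r >= n)
    stop("grid too small for the requested blur kernel")
  ii <- jj <- integer(0); xx <- numeric(0)
  for (o in (-r):r) {
    i <- seq_len(n)
    j <- i + o
    j <- ifelse(j < 1L, 1L - j, ifelse(j > n, 2L * n + 1L - j, j))
    ii <- c(ii, i); jj <- c(jj, j); xx <- c(xx, rep(k[o + r + 1L], n))
  }
  G <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  .convCache[[key]] <- G
  G
}

# in-plane blur of an (nx*ny) x nz matrix of stacked slices
.blurXY <- function(X, Gx, Gy, nx, ny) {
  nz <- ncol(X)
  V <- array(as.numeric(Gx %*% matrix(X, nx, ny * nz)), c(nx, ny, nz))
  V <- aperm(V, c(2, 1, 3))
  V <- array(as.numeric(Gy %*% matrix(V, ny, nx * nz)), c(ny, nx, nz))
  matrix(aperm(V, c(2, 1, 3)), nx * ny, nz)
}

# forward/adjoint in-plane blur operator pair for a grid
.blurOperator <- function(grid, fwhm) {
  if (fwhm == 0)
    return(list(fw = identity, bw = identity))
  Gx <- .convMatrix1d(grid@nx, fwhm, grid@dx)
  Gy <- .convMatrix1d(grid@ny, fwhm, grid@dy)
  nx <- grid@nx; ny <- grid@ny
  list(fw = function(X) .blurXY(X, Gx, Gy, nx, ny),
       bw = function(X) .blurXY(X, Matrix::t(Gx), Matrix::t(Gy), nx, ny))
}

#' @rdname applyPsf
#' @export
setMethod("applyPsf", signature("ActivityVolume", "numeric"),
  function(x, fwhm, ...) {
    if (fwhm < 0) stop("fwhm must be >= 0")
    if (fwhm == 0) return(x)
    g <- x@grid
    op <- .blurOperator(g, fwhm)
    X <- op$fw(matrix(x@values, g@nx * g@ny, g@nz))
    ActivityVolume(array(pmax(X, 0), c(g@nx, g@ny, g@nz)), g,
                   suvScale = x@suvScale)
  })

#' @rdname applyPsf
#' @export
setMethod("applyPsf", signature("Sinogram", "numeric"),
  function(x, fwhm, ...) {
    if (fwhm < 0) stop("fwhm must be >= 0")
    if (fwhm == 0) return(x)
    geom <- x@geometry
    G <- .convMatrix1d(geom@nBins, fwhm, geom@binWidth)
    d <- dim(x@values)
    Y <- as.matrix(G %*% matrix(x@values, d[1], d[2] * d[3]))
    Sinogram(array(pmax(Y, 0), d), geom, kind = x@kind, meta = x@meta)
  })
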