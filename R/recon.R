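# OSEM and one-step-late TV-penalized EM reconstruction.
#
# Both algorithms share one multiplicative-update core; OSEM is the beta = 0
# path (plus a Gaussian post-filter), so the beta -> 0 reduction is exact by
# construction. The penalty enters one-step-late: the subset EM denominator
# s_k is augmented with the epsilon-smoothed total-variation gradient of the
# current image, scaled by an effective penalization factor
#   beta_eff = beta * kappa * sqrt(necReferenceCounts / totalCounts) * w_j
# where w_j is the normalized local sensitivity weight. The denominator is
# floored at 0.1 * s_k, which keeps updates positive when the (possibly
# negative) penalty gradient is large.

# gradient of R(x) = sum_v sqrt(|grad x|^2 + eps^2), forward differences,
# replicated boundary; 3D when the volume has more than one slice
.tvGrad <- function(V, eps) {
  d <- dim(V); nx <- d[1]; ny <- d[2]; nz <- d[3]
  dxA <- V[c(2:nx, nx), , , drop = FALSE] - V
  dyA <- V[, c(2:ny, ny), , drop = FALSE] - V
  m2 <- dxA^2 + dyA^2
  if (nz > 1L) {
    dzA <- V[, , c(2:nz, nz), drop = FALSE] - V
    m2 <- m2 + dzA^2
  }
  m <- sqrt(m2 + eps^2)
  px <- dxA / m; py <- dyA / m
  g <- -(px + py)
  if (nz > 1L) {
    pz <- dzA / m
    g <- g - pz
    g[, , 2:nz] <- g[, , 2:nz] + pz[, , 1:(nz - 1)]
  }
  g[2:nx, , ] <- g[2:nx, , ] + px[1:(nx - 1), , ]
  g[, 2:ny, ] <- g[, 2:ny, ] + py[, 1:(ny - 1), ]
  g
}

.emCore <- function(counts, grid, geometry, iterations, subsets,
                    modelPsfFwhm, beta = 0, kappa = 1, necRef = 1,
                    sensW = TRUE, tvEpsRel = 1e-3, stopTol = 0,
                    denomFloor = 0.1) {
  if (counts@kind != "counts") stop("reconstruction needs a counts sinogram")
  if (beta < 0) stop("beta must be >= 0")
  op <- .systemOperator(grid, geometry, subsets)
  blur <- .blurOperator(grid, modelPsfFwhm)
  nx <- grid@nx; ny <- grid@ny; nz <- grid@nz
  nxy <- nx * ny
  if (dim(counts@values)[3] != nz)
    stop("sinogram slice count does not match the grid")
  Y <- matrix(counts@values, geometry@nBins * geometry@nAngles, nz)

  sens <- lapply(op$split$Atsub, function(At)
    as.numeric(blur$bw(matrix(as.numeric(At %*% rep(1, ncol(At))), nxy, 1))))
  sTot <- Reduce(`+`, sens)
  fov <- sTot > 1e-12 * max(sTot)

  totalCounts <- sum(Y)
  x0 <- if (totalCounts > 0) totalCounts / (sum(sTot) * nz) else 0
  X <- matrix(0, nxy, nz)
  X[fov, ] <- x0
  eps <- tvEpsRel * max(x0, 1e-12)  # fixed for the whole run

  betaScale <- 0
  if (beta > 0 && totalCounts > 0)
    betaScale <- beta * kappa * sqrt(necRef / totalCounts) / subsets
  w <- if (sensW) sTot / mean(sTot[fov]) else rep(1, nxy)

  trace <- numeric(0)
  for (it in seq_len(iterations)) {
    Xprev <- X
    for (k in seq_len(subsets)) {
      Xb <- blur$fw(X)
      Yh <- as.matrix(op$split$Asub[[k]] %*% Xb)
      Rat <- Y[op$split$rows[[k]], , drop = FALSE] / Yh
      Rat[Yh <= 0] <- 0
      Bp <- blur$bw(as.matrix(op$split$Atsub[[k]] %*% Rat))
      sk <- sens[[k]]
      if (betaScale > 0) {
        gR <- .tvGrad(array(X, c(nx, ny, nz)), eps)
        denom <- sk + betaScale * (w * matrix(gR, nxy, nz))
      } else {
        denom <- matrix(sk, nxy, nz)
      }
      denom <- pmax(denom, denomFloor * sk)
      upd <- Bp / denom
      upd[sk <= 0, ] <- 0
      X <- X * upd
    }
    nPrev <- sqrt(sum(Xprev^2))
    relch <- if (nPrev > 0) sqrt(sum((X - Xprev)^2)) / nPrev else 0
    trace <- c(trace, relch)
    if (stopTol > 0 && relch < stopTol) break
  }
  list(X = X, trace = trace)
}

.asReconResult <- function(fit, grid, protocol, label, suvScale,
                           postFilterFwhm = 0, countScale = 1) {
  img <- ActivityVolume(array(pmax(fit$X, 0) / countScale,
                              c(grid@nx, grid@ny, grid@nz)),
                        grid, suvScale = suvScale)
  if (postFilterFwhm > 0) img <- applyPsf(img, postFilterFwhm)
  new("ReconResult", image = img, protocol = protocol, trace = fit$trace,
      label = label)
}

#' OSEM reconstruction
#'
#' Standard ordered-subset EM: multiplicative updates from a uniform positive
#' initialization inside the field of view, with the Gaussian resolution model
#' in the forward projector, followed by a Gaussian post-filter. Defaults are
#' the standard clinical protocol (2 iterations, 20 subsets, 3 mm filter).
#'
#' @param counts a counts-kind [Sinogram-class].
#' @param protocol an [OsemProtocol-class].
#' @param grid the reconstruction [VoxelGrid-class].
#' @param geometry the [ProjectionGeometry-class] of the data.
#' @param label optional [GroupLabel-class].
#' @param suvScale SUV calibration to stamp on the image (default 1).
#' @return a [ReconResult-class].
#' @export
osemReconstruct <- function(counts, protocol = OsemProtocol(), grid, geometry,
                            label = new("GroupLabel"), suvScale = 1) {
  fit <- .emCore(counts, grid, geometry,
                 iterations = protocol@iterations, subsets = protocol@subsets,
                 modelPsfFwhm = protocol@modelPsfFwhm, beta = 0)
  .asReconResult(fit, grid, protocol, label, suvScale,
                 postFilterFwhm = protocol@postFilterFwhm,
                 countScale = .countScaleOf(counts))
}

#' One-step-late TV-penalized EM reconstruction
#'
#' Penalized EM with the epsilon-smoothed total-variation gradient evaluated
#' at the current image inside the EM denominator (one-step-late), an
#' effective penalty scaled by the global constant `kappa`, the
#' count-dependent factor sqrt(necReferenceCounts / totalCounts) and the
#' normalized local sensitivity weight. No post-filter is applied. With
#' `beta = 0` the result is bit-for-bit identical to unfiltered OSEM on the
#' same schedule (shared code path).
#'
#' @inheritParams osemReconstruct
#' @param protocol a [PemProtocol-class].
#' @return a [ReconResult-class].
#' @export
pemReconstruct <- function(counts, protocol, grid, geometry,
                           label = new("GroupLabel"), suvScale = 1) {
  fit <- .emCore(counts, grid, geometry,
                 iterations = protocol@iterations, subsets = protocol@subsets,
                 modelPsfFwhm = protocol@modelPsfFwhm, beta = protocol@beta,
                 kappa = protocol@kappa,
                 necRef = protocol@necReferenceCounts,
                 sensW = protocol@sensitivityWeighting,
                 tvEpsRel = protocol@tvEpsilonRel, stopTol = protocol@stopTol)
  .asReconResult(fit, grid, protocol, label, suvScale, postFilterFwhm = 0,
                 countScale = .countScaleOf(counts))
}

# calibration factor stamped by poissonAcquire (1 when absent, e.g. for
# directly constructed count sinograms)
.countScaleOf <- function(counts) {
  cs <- counts@meta$countScale
  if (is.null(cs) || !is.finite(cs) || cs <= 0) 1 else cs
}

# --- group labels -----------------------------------------------------------

.formatGroupLabel <- function(algorithm, durationClass, beta = NA_real_) {
  if (algorithm == "OSEM") return(sprintf("O%d", as.integer(durationClass)))
  if (algorithm == "PEM") {
    if (is.na(beta)) stop("penalized labels need beta")
    return(sprintf("HR%d.%s", as.integer(durationClass),
                   sub("^0\\.", "", format(beta))))
  }
  stop(sprintf("unknown algorithm tag '%s'", algorithm))
}

#' Build or parse reconstruction-arm labels
#'
#' `makeGroupLabel()` maps (algorithm, duration class, beta) to the
#' conventional label: OSEM at d m/b is `O{d}`; the penalized algorithm is
#' `HR{d}.{beta}` with the leading "0." of beta dropped (`HR2.03`, `HR3.5`).
#' `parseGroupLabel()` inverts it.
#'
#' @param algorithm `"OSEM"` or `"PEM"`.
#' @param durationClass 2 or 3.
#' @param beta penalization factor (required for `"PEM"`).
#' @return a [GroupLabel-class].
#' @examples
#' makeGroupLabel("OSEM", 3)        # O3
#' makeGroupLabel("PEM", 2, 0.03)   # HR2.03
#' @export
makeGroupLabel <- function(algorithm, durationClass, beta = NA_real_) {
  txt <- .formatGroupLabel(algorithm, durationClass, beta)
  new("GroupLabel", label = txt, algorithm = algorithm,
      durationClass = durationClass,
      beta = if (algorithm == "OSEM") NA_real_ else beta)
}

#' @rdname makeGroupLabel
#' @param text a label string such as `"O3"` or `"HR2.03"`.
#' @export
parseGroupLabel <- function(text) {
  if (grepl("^O[23]$", text))
    return(makeGroupLabel("OSEM", as.numeric(substring(text, 2))))
  m <- regmatches(text, regexec("^HR([23])\\.([0-9]+)$", text))[[1]]
  if (length(m) == 3)
    return(makeGroupLabel("PEM", as.numeric(m[2]),
                          as.numeric(paste0("0.", m[3]))))
  stop(sprintf("unrecognized group label '%s'", text))
}
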