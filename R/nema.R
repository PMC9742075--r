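# NEMA-style phantom evaluation: ROI layout, contrast recovery, background
# variability, CNR, RCR, normalized activity.

#' Lay out NEMA-style evaluation ROIs
#'
#' One circular ROI per hot sphere, concentric with the simulation-truth
#' center and matched to the sphere diameter, plus `nBackground` background
#' ROIs per sphere size at equal angular spacing on a ring in the peripheral
#' background of the central slice. Background ROIs of different sizes share
#' the 12 ring centers (concentric, the NEMA convention); within each size
#' they must not overlap, must stay inside the body, and must keep at least
#' `clearanceMm` edge-to-edge from every sphere.
#'
#' @param spec the [PhantomSpec-class] (supplies truth geometry).
#' @param grid the [VoxelGrid-class].
#' @param nBackground background ROIs per sphere size (default 12).
#' @param ringRadius radius (mm) of the background-ROI ring (default 95).
#' @param clearanceMm minimum sphere-to-ROI edge clearance (default 15).
#' @return an [RoiLayout-class].
#' @export
layoutRois <- function(spec, grid, nBackground = 12L, ringRadius = 95,
                       clearanceMm = 15) {
  validObject(spec)
  nd <- length(spec@sphereDiameters)
  sphereRois <- data.frame(sphere = seq_len(nd),
                           cx = spec@sphereCenters[, 1],
                           cy = spec@sphereCenters[, 2],
                           diameter = spec@sphereDiameters)
  ang <- (seq_len(nBackground) - 1) * 2 * pi / nBackground + pi / 12
  bg <- do.call(rbind, lapply(seq_len(nd), function(j) {
    data.frame(sphere = j, roi = seq_len(nBackground),
               cx = ringRadius * cos(ang), cy = ringRadius * sin(ang),
               diameter = spec@sphereDiameters[j])
  }))

  a <- spec@bodySemiAxes[1]; b <- spec@bodySemiAxes[2]
  for (i in seq_len(nrow(bg))) {
    rr <- bg$diameter[i] / 2
    if ((bg$cx[i] / (a - rr))^2 + (bg$cy[i] / (b - rr))^2 > 1)
      stop("background ROI extends outside the body outline; shrink ringRadius")
    edge <- sqrt((bg$cx[i] - spec@sphereCenters[, 1])^2 +
                 (bg$cy[i] - spec@sphereCenters[, 2])^2) -
            spec@sphereDiameters / 2 - rr
    if (any(edge < clearanceMm))
      stop("background ROI closer than the required clearance to a sphere")
  }
  # non-overlap within each size set
  for (j in seq_len(nd)) {
    sub <- bg[bg$sphere == j, ]
    dmat <- as.matrix(dist(sub[, c("cx", "cy")]))
    diag(dmat) <- Inf
    if (any(dmat < sub$diameter[1]))
      stop("background ROIs of one size overlap; too many ROIs for the ring")
  }
  # the grid must actually contain the ring
  if (ringRadius + max(spec@sphereDiameters) / 2 >
        min(grid@nx * grid@dx, grid@ny * grid@dy) / 2)
    stop("grid too small to place the background ROI ring")
  new("RoiLayout", sphereRois = sphereRois, backgroundRois = bg,
      clearanceMm = clearanceMm)
}

# mean of image values over a circular ROI on the central slice
.roiMean <- function(vals, grid, cx, cy, diameter) {
  co <- .gridCoords(grid)
  kz <- (grid@nz + 1L) %/% 2L
  m <- outer((co$x - cx)^2, (co$y - cy)^2, "+") <= (diameter / 2)^2
  if (!any(m)) stop("ROI contains no voxel centers")
  mean(vals[, , kz][m])
}

#' Percent contrast recovery of a hot sphere
#'
#' `CR = (C_H/C_B - 1) / (a_H/a_B - 1) * 100`, the measured contrast relative
#' to the true fill contrast.
#'
#' @param cH mean counts in the sphere ROI.
#' @param cB mean over the background ROI means.
#' @param aH,aB true activity concentrations in sphere and background.
#' @return percent CR.
#' @examples
#' contrastRecovery(10, 4, 13.2, 3.3)  # 50
#' @export
contrastRecovery <- function(cH, cB, aH, aB) {
  if (cB <= 0) stop("background mean must be > 0")
  if (aH == aB) stop("true contrast is undefined when aH == aB")
  (cH / cB - 1) / (aH / aB - 1) * 100
}

#' Percent background variability
#'
#' `BV = SD/C_B * 100` with SD the standard deviation across the background
#' ROI means.
#'
#' @param sdB standard deviation of the background ROI means (>= 0).
#' @param cB mean over the background ROI means (> 0).
#' @return percent BV.
#' @export
backgroundVariability <- function(sdB, cB) {
  if (cB <= 0) stop("background mean must be > 0")
  if (sdB < 0) stop("standard deviation must be >= 0")
  sdB / cB * 100
}

#' Contrast-to-noise ratio
#'
#' CR divided by BV (both in percent), a measure of signal level in the
#' presence of noise.
#'
#' @param cr percent contrast recovery.
#' @param bv percent background variability (> 0).
#' @return dimensionless CNR.
#' @export
cnr <- function(cr, bv) {
  if (bv == 0) stop("CNR is undefined at zero background variability")
  cr / bv
}

#' Radioactivity concentration ratio
#'
#' Measured sphere-to-background concentration ratio; bounded above by the
#' true fill ratio under partial-volume losses.
#'
#' @param sphereConc measured sphere concentration.
#' @param backgroundConc measured background concentration (> 0).
#' @return dimensionless RCR.
#' @examples
#' rcr(13.2, 3.3)  # 4
#' @export
rcr <- function(sphereConc, backgroundConc) {
  if (backgroundConc <= 0) stop("background concentration must be > 0")
  sphereConc / backgroundConc
}

# ratio of each group's value to the reference group's value
.normalizeByReference <- function(valuesByGroup, reference) {
  if (!reference %in% names(valuesByGroup))
    stop(sprintf("reference group '%s' missing", reference))
  ref <- valuesByGroup[[reference]]
  if (!is.finite(ref) || ref <= 0)
    stop("reference group value must be positive")
  out <- vapply(valuesByGroup, function(v) v / ref, numeric(1))
  out[reference] <- 1.0  # exact by definition
  out
}

#' Normalized activity relative to a reference group
#'
#' Each group's mean sphere concentration divided by the reference group's
#' (default O3); the reference maps to exactly 1.
#'
#' @param groupMeans named numeric vector (or list) of per-group sphere mean
#'   concentrations.
#' @param reference reference group label (default `"O3"`).
#' @return named numeric vector of dimensionless ratios.
#' @export
normalizedActivity <- function(groupMeans, reference = "O3") {
  .normalizeByReference(as.list(groupMeans), reference)
}

#' Measure NEMA sphere metrics on a reconstructed image
#'
#' For each hot sphere: the sphere-ROI mean `C_H`, the mean `C_B` and
#' population standard deviation `SD` across the background ROI means, and
#' the derived percent CR, percent BV, CNR and RCR. Voxel membership is by
#' voxel center; the same rule for sphere and background ROIs lets membership
#' biases cancel in `C_H/C_B`.
#'
#' @param image an [ActivityVolume-class] or [ReconResult-class].
#' @param layout an [RoiLayout-class] from [layoutRois()].
#' @param spec the [PhantomSpec-class] (true concentrations).
#' @param sdType `"population"` (default) or `"sample"`.
#' @return data.frame with one row per sphere: sphere, diameter, cH, cB, sd,
#'   cr, bv, cnr, rcr.
#' @export
measureSphereMetrics <- function(image, layout, spec,
                                 sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  if (is(image, "ReconResult")) image <- image@image
  vals <- image@values; grid <- image@grid
  out <- lapply(seq_len(nrow(layout@sphereRois)), function(j) {
    sr <- layout@sphereRois[j, ]
    cH <- .roiMean(vals, grid, sr$cx, sr$cy, sr$diameter)
    bgj <- layout@backgroundRois[layout@backgroundRois$sphere == sr$sphere, ]
    means <- vapply(seq_len(nrow(bgj)), function(i)
      .roiMean(vals, grid, bgj$cx[i], bgj$cy[i], bgj$diameter[i]), numeric(1))
    cB <- mean(means)
    sdB <- if (sdType == "population")
      sqrt(mean((means - cB)^2)) else sd(means)
    cr <- contrastRecovery(cH, cB, spec@sphereConcentration,
                           spec@backgroundConcentration)
    bv <- backgroundVariability(sdB, cB)
    data.frame(sphere = sr$sphere, diameter = sr$diameter, cH = cH, cB = cB,
               sd = sdB, cr = cr, bv = bv,
               cnr = if (bv > 0) cnr(cr, bv) else NA_real_,
               rcr = rcr(cH, cB))
  })
  do.call(rbind, out)
}
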