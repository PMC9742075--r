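# Clinical quantitation: liver VOI noise, threshold lesion segmentation,
# SUVmax, equivalent diameter, normalization and stratification.

# logical mask of voxel centers within a sphere (any slice)
.ballMask <- function(grid, center, radius) {
  co <- .gridCoords(grid)
  m <- array(FALSE, c(grid@nx, grid@ny, grid@nz))
  dz2 <- (co$z - center[3])^2
  dx2 <- (co$x - center[1])^2
  dy2 <- (co$y - center[2])^2
  for (k in seq_len(grid@nz)) {
    m[, , k] <- outer(dx2, dy2, "+") + dz2[k] <= radius^2
  }
  m
}

#' Liver noise measurement in a spherical VOI
#'
#' SUV mean and SD over the voxels of a 3-cm (default) spherical VOI, and the
#' percent coefficient of variation `CV = SUV_sd / SUV_mean * 100`. The SD is
#' the population SD by default. If `patient` is given, the VOI must fit
#' entirely inside the liver compartment.
#'
#' @param image an [ActivityVolume-class] or [ReconResult-class] with a valid
#'   `suvScale`.
#' @param voiCenter VOI center (mm, length 3); default: the liver center of
#'   `patient`.
#' @param voiDiameter VOI diameter in mm (default 30).
#' @param patient optional [PatientSpec-class] used to check VOI containment.
#' @param sdType `"population"` (default) or `"sample"`.
#' @return list with `suvMean`, `suvSd`, `cv` (percent), `nVoxels`.
#' @export
liverCv <- function(image, voiCenter = NULL, voiDiameter = 30,
                    patient = NULL, sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  if (is(image, "ReconResult")) image <- image@image
  if (is.null(voiCenter)) {
    if (is.null(patient)) stop("voiCenter or patient must be given")
    voiCenter <- patient@liverCenter
  }
  r <- voiDiameter / 2
  if (!is.null(patient)) {
    off <- abs(voiCenter - patient@liverCenter)
    ax <- patient@liverSemiAxes
    if (any(ax <= r) || sum((off / (ax - r))^2) > 1)
      stop("liver VOI extends outside the liver compartment")
  }
  m <- .ballMask(image@grid, voiCenter, r)
  if (!any(m)) stop("VOI contains no voxel centers")
  suv <- image@values[m] / image@suvScale
  mu <- mean(suv)
  sdv <- if (sdType == "population") sqrt(mean((suv - mu)^2)) else sd(suv)
  if (mu <= 0) stop("VOI mean SUV must be positive for a CV")
  list(suvMean = mu, suvSd = sdv, cv = sdv / mu * 100, nVoxels = sum(m))
}

#' Normalized CV relative to a reference group
#'
#' Ratio of each group's liver CV to the reference group's CV (default O3);
#' the reference maps to exactly 1.
#'
#' @param cvByGroup named numeric vector (or list) of per-group CVs.
#' @param reference reference label (default `"O3"`).
#' @return named numeric vector.
#' @examples
#' normalizedCv(c(O3 = 12.88, O2 = 14.36))[["O2"]]  # 1.115
#' @export
normalizedCv <- function(cvByGroup, reference = "O3") {
  .normalizeByReference(as.list(cvByGroup), reference)
}

#' Equivalent diameter of a lesion volume
#'
#' Diameter of the sphere with the same volume: `D = (6 V / pi)^(1/3)`.
#'
#' @param volumeMm3 segmented volume in mm3 (>= 0).
#' @return diameter in mm.
#' @examples
#' equivalentDiameter(pi / 6 * 1000)  # 10
#' @export
equivalentDiameter <- function(volumeMm3) {
  if (any(volumeMm3 < 0)) stop("volume must be >= 0")
  (6 * volumeMm3 / pi)^(1 / 3)
}

# 26-connected component of `mask` containing linear voxel index `start`
.connectedComponent <- function(mask, start) {
  d <- dim(mask)
  comp <- array(FALSE, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  idx <- arrayInd(start, d)
  frontier <- idx
  comp[start] <- TRUE
  while (nrow(frontier) > 0) {
    nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i)
      sweep(frontier, 2, offs[i, ], "+")))
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    if (!nrow(nb)) break
    lin <- nb[, 1] + (nb[, 2] - 1) * d[1] + (nb[, 3] - 1) * d[1] * d[2]
    lin <- unique(lin[mask[lin] & !comp[lin]])
    if (!length(lin)) break
    comp[lin] <- TRUE
    frontier <- arrayInd(lin, d)
  }
  comp
}

#' Threshold-based lesion segmentation
#'
#' Semi-automatic 3D segmentation around a seed point: SUVmax is the maximum
#' within a search ball (default radius 15 mm) around the seed; the
#' segmentation is the 26-connected component of voxels at or above
#' `thresholdFraction * SUVmax` (default 41 percent) containing the maximum
#' voxel. Volume is voxel count times voxel volume; the equivalent diameter
#' derives from it.
#'
#' Errors when the seed sits in flat background, i.e. SUVmax does not exceed
#' 1.2 times the local background median within the search ball.
#'
#' @param image an [ActivityVolume-class] or [ReconResult-class].
#' @param seedMm seed point (mm, length 3).
#' @param thresholdFraction fraction of SUVmax (default 0.41).
#' @param searchRadius local search-ball radius in mm (default 15).
#' @return list with `suvMax`, `volumeMm3`, `equivalentDiameter`, `nVoxels`,
#'   `threshold` (SUV), `maxIndex` (linear voxel index).
#' @export
segmentLesion <- function(image, seedMm, thresholdFraction = 0.41,
                          searchRadius = 15) {
  if (is(image, "ReconResult")) image <- image@image
  if (thresholdFraction <= 0 || thresholdFraction > 1)
    stop("thresholdFraction must be in (0, 1]")
  grid <- image@grid
  suv <- image@values / image@suvScale
  ball <- .ballMask(grid, seedMm, searchRadius)
  if (!any(ball)) stop("search ball contains no voxel centers")
  suvMax <- max(suv[ball])
  localMedian <- median(suv[ball])
  if (suvMax <= 1.2 * localMedian)
    stop("degenerate lesion: no distinguishable maximum near the seed")
  maxIdx <- which(ball & suv == suvMax)[1]
  thr <- thresholdFraction * suvMax
  mask <- suv >= thr
  comp <- .connectedComponent(mask, maxIdx)
  nVox <- sum(comp)
  vol <- nVox * .voxelVolume(grid)
  list(suvMax = suvMax, volumeMm3 = vol,
       equivalentDiameter = equivalentDiameter(vol), nVoxels = nVox,
       threshold = thr, maxIndex = maxIdx)
}

#' Per-lesion SUVmax normalization against a reference group
#'
#' Each lesion's SUVmax in each group is divided by the same lesion's SUVmax
#' in the reference group; group summaries are the mean and SD of those
#' per-lesion ratios (mean-of-ratios convention, which is why the reference
#' group reports an SD of exactly 0).
#'
#' @param suvmaxByGroup a lesions x groups numeric matrix (dimnames required)
#'   of SUVmax values.
#' @param reference reference group label (default `"O3"`).
#' @return list with `ratios` (lesions x groups matrix) and `summary`
#'   (data.frame: group, mean, sd).
#' @export
normalizedSuvmax <- function(suvmaxByGroup, reference = "O3") {
  if (is.null(colnames(suvmaxByGroup)))
    stop("suvmaxByGroup needs group column names")
  if (!reference %in% colnames(suvmaxByGroup))
    stop(sprintf("reference group '%s' missing", reference))
  ref <- suvmaxByGroup[, reference]
  if (any(!is.finite(ref) | ref <= 0))
    stop("every lesion needs a positive reference-group SUVmax")
  ratios <- sweep(suvmaxByGroup, 1, ref, "/")
  ratios[, reference] <- 1.0
  summary <- data.frame(group = colnames(ratios),
                        mean = colMeans(ratios),
                        sd = apply(ratios, 2, sd),
                        row.names = NULL)
  list(ratios = ratios, summary = summary)
}

#' Stratify a lesion / patient into the analysis classes
#'
#' Size classes by equivalent diameter with half-open intervals
#' (small `[0,10)`, medium `[10,20)`, large `[20,Inf)` mm); injected-activity
#' classes split at 1.60 MBq/kg (1.60 is "high"); BMI classes split at
#' 24 kg/m2 (24 is "overweight").
#'
#' @param equivalentDiameterMm lesion equivalent diameter D, mm.
#' @param iaPerKg injected activity per kg, MBq/kg.
#' @param bmi body-mass index, kg/m2.
#' @return list with `sizeClass`, `iaClass`, `bmiClass` (factors/characters;
#'   classes for missing inputs are NA).
#' @examples
#' stratify(9.9, 1.59, 23.9)   # small / low / normal_or_under
#' stratify(10.0, 1.60, 24.0)  # medium / high / overweight
#' @export
stratify <- function(equivalentDiameterMm = NA, iaPerKg = NA, bmi = NA) {
  sizeClass <- if (is.na(equivalentDiameterMm)) NA_character_ else
    as.character(cut(equivalentDiameterMm, c(0, 10, 20, Inf), right = FALSE,
                     labels = c("small", "medium", "large")))
  iaClass <- if (is.na(iaPerKg)) NA_character_ else
    if (iaPerKg >= 1.60) "high" else "low"
  bmiClass <- if (is.na(bmi)) NA_character_ else
    if (bmi >= 24) "overweight" else "normal_or_under"
  list(sizeClass = sizeClass, iaClass = iaClass, bmiClass = bmiClass)
}
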