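# Synthetic patient-like volume generation.

#' Construct a lesion specification
#'
#' @param center lesion center (mm, length 3, relative to grid center).
#' @param diameter true diameter, mm.
#' @param suv lesion SUV (must exceed the body-background SUV of the patient
#'   it is placed in).
#' @param tissue context tag: `"lung"`, `"bone"`, `"lymph_node"` or
#'   `"soft_tissue"`.
#' @return a [LesionSpec-class] object.
#' @export
LesionSpec <- function(center, diameter, suv, tissue = "soft_tissue") {
  new("LesionSpec", center = center, diameter = diameter, suv = suv,
      tissue = tissue)
}

#' Construct a synthetic patient specification
#'
#' Defaults emulate the reference cohort conditions: 61.3 kg body weight with
#' 97.2 MBq injected (1.59 MBq/kg), a uniform liver at SUV 5.96 and a
#' soft-tissue background at SUV 1. The default lesion set spans the three
#' size strata (8, 14 and 25 mm) at SUV 10; lesion uptake is a free parameter
#' of the generator.
#'
#' @param weightKg body weight, kg.
#' @param heightM height, m (default set so BMI is just under 24 kg/m2).
#' @param injectedActivityMBq injected activity, MBq.
#' @param bodySemiAxes in-plane body ellipse semi-axes, mm.
#' @param liverCenter,liverSemiAxes liver ellipsoid geometry, mm.
#' @param liverSuv uniform liver SUV.
#' @param backgroundSuv body-background SUV.
#' @param lesions list of [LesionSpec-class]; `list()` for none.
#' @param voiDiameter liver noise-VOI diameter, mm (lesions may not intrude
#'   into this placement region).
#' @return a [PatientSpec-class] object.
#' @examples
#' p <- PatientSpec()
#' p@injectedActivityMBq / p@weightKg        # ~1.59 MBq/kg
#' round(suvScaleOf(p), 3)                   # 1.586 kBq/mL per SUV
#' @export
PatientSpec <- function(weightKg = 61.3, heightM = 1.60,
                        injectedActivityMBq = 97.2,
                        bodySemiAxes = c(150, 100),
                        liverCenter = c(55, 10, 0),
                        liverSemiAxes = c(60, 45, 25),
                        liverSuv = 5.96, backgroundSuv = 1,
                        lesions = defaultLesions(),
                        voiDiameter = 30) {
  new("PatientSpec", weightKg = weightKg, heightM = heightM,
      injectedActivityMBq = injectedActivityMBq, bodySemiAxes = bodySemiAxes,
      liverCenter = liverCenter, liverSemiAxes = liverSemiAxes,
      liverSuv = liverSuv, backgroundSuv = backgroundSuv, lesions = lesions,
      voiDiameter = voiDiameter)
}

#' Default synthetic lesion set
#'
#' Three spherical lesions spanning the size strata used for stratified
#' analysis: small (8 mm), medium (14 mm) and large (25 mm), all at SUV 10,
#' placed in the body background away from the liver.
#'
#' @param suv lesion SUV shared by all three (default 10).
#' @return list of [LesionSpec-class].
#' @export
defaultLesions <- function(suv = 10) {
  list(LesionSpec(c(-70, -40, 0), 8,  suv, "lymph_node"),
       LesionSpec(c(-40,  60, 0), 14, suv, "bone"),
       LesionSpec(c(-90,  20, 0), 25, suv, "soft_tissue"))
}

#' SUV calibration factor of a patient
#'
#' `suvScale = IA[kBq] / weight[g]` (kBq/mL per SUV unit, assuming unit tissue
#' density), so that SUV(v) = concentration(v) / suvScale.
#'
#' @param spec a [PatientSpec-class].
#' @return numeric scalar, kBq/mL per SUV.
#' @export
suvScaleOf <- function(spec) {
  spec@injectedActivityMBq * 1000 / (spec@weightKg * 1000)
}

#' Body-mass index of a patient specification
#' @param spec a [PatientSpec-class].
#' @return BMI in kg/m2.
#' @export
bmiOf <- function(spec) spec@weightKg / spec@heightM^2

#' Build a synthetic patient volume
#'
#' Returns a concentration volume (kBq/mL) with
#' `suvScale = IA[kBq]/weight[g]`: liver voxels at the liver SUV, lesion
#' voxels at their lesion SUV, remaining body voxels at the background SUV,
#' outside-body voxels 0. Boundary voxels carry sub-voxel mixtures in
#' `"subsample"` mode (see [buildNemaPhantom()]).
#'
#' Errors if a lesion intrudes into the liver noise-VOI placement region,
#' which would contaminate the liver noise measurement, or if a lesion or the
#' liver extends outside the body.
#'
#' @param spec a [PatientSpec-class].
#' @param grid a [VoxelGrid-class] (a multi-slice slab; default patient grid
#'   is `VoxelGrid(nz = 20L)`).
#' @param boundary `"subsample"` or `"binary"`.
#' @return an [ActivityVolume-class].
#' @export
buildPatient <- function(spec, grid, boundary = c("subsample", "binary")) {
  boundary <- match.arg(boundary)
  validObject(spec); validObject(grid)
  sc <- suvScaleOf(spec)
  a <- spec@bodySemiAxes[1]; b <- spec@bodySemiAxes[2]

  # liver inside body (in-plane, conservative) and inside the axial slab
  lc <- spec@liverCenter; ls <- spec@liverSemiAxes
  if ((abs(lc[1]) / (a - ls[1]))^2 + (abs(lc[2]) / (b - ls[2]))^2 > 1)
    stop("liver extends outside the body outline")
  halfZ <- grid@nz * grid@dz / 2
  if (abs(lc[3]) + ls[3] > halfZ)
    stop("liver extends outside the axial extent of the grid")

  voiR <- spec@voiDiameter / 2
  for (les in spec@lesions) {
    r <- les@diameter / 2
    if ((abs(les@center[1]) + r) / a > 1 ||
        ((les@center[1] / (a - r))^2 + (les@center[2] / (b - r))^2) > 1)
      stop("lesion extends outside the body outline")
    # keep the liver noise VOI clean: no lesion within VOI radius + lesion
    # radius of the VOI center (the liver center)
    if (sqrt(sum((les@center - lc)^2)) < voiR + r + grid@dx)
      stop("lesion overlaps the liver VOI placement region")
  }

  body <- .ellipseFraction(grid, spec@bodySemiAxes, boundary)
  vals <- body * (spec@backgroundSuv * sc)
  liver <- .ellipsoidFraction(grid, lc, ls, boundary)
  vals <- vals + liver * (spec@liverSuv - spec@backgroundSuv) * sc
  for (les in spec@lesions) {
    fl <- .sphereFraction(grid, les@center, les@diameter / 2, boundary)
    vals <- vals + fl * (les@suv - spec@backgroundSuv) * sc
  }
  ActivityVolume(vals, grid, suvScale = sc)
}
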