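# Core S4 value classes: voxel grids, activity volumes, phantom/patient
# specifications, projection geometry, sinograms, reconstruction protocols.

#' VoxelGrid: regular voxel lattice geometry
#'
#' Describes a regular 3D voxel lattice. Physical positions are voxel centers,
#' in mm, relative to the grid center; axial slices run along z. The default
#' matches the clinical reconstruction grid used throughout the package:
#' 192 x 192 in-plane at 3.12 mm pixels and 2.68 mm slices.
#'
#' @slot nx,ny,nz integer voxel counts along x, y, z.
#' @slot dx,dy numeric in-plane voxel size (mm).
#' @slot dz numeric slice thickness (mm).
#' @export
setClass("VoxelGrid",
  representation(nx = "integer", ny = "integer", nz = "integer",
                 dx = "numeric", dy = "numeric", dz = "numeric"),
  prototype(nx = 192L, ny = 192L, nz = 1L, dx = 3.12, dy = 3.12, dz = 2.68))

setValidity("VoxelGrid", function(object) {
  if (any(c(object@nx, object@ny, object@nz) < 1L))
    return("voxel counts must all be >= 1")
  if (any(c(object@dx, object@dy, object@dz) <= 0))
    return("voxel spacings must all be > 0")
  TRUE
})

#' ActivityVolume: voxelized activity-concentration image
#'
#' A voxel image of activity concentration (kBq/mL) on a [VoxelGrid], together
#' with the SUV calibration factor `suvScale` (kBq/mL per SUV unit), so that
#' SUV(v) = concentration(v) / suvScale.
#'
#' @slot values numeric array (nx x ny x nz) of concentrations, all >= 0.
#' @slot grid a [VoxelGrid].
#' @slot suvScale numeric, kBq/mL per unit SUV; > 0.
#' @export
setClass("ActivityVolume",
  representation(values = "array", grid = "VoxelGrid", suvScale = "numeric"),
  prototype(suvScale = 1))

setValidity("ActivityVolume", function(object) {
  d <- dim(object@values)
  g <- object@grid
  if (length(d) != 3L || !all(d == c(g@nx, g@ny, g@nz)))
    return("values must be an nx x ny x nz array matching the grid")
  if (any(object@values < 0)) return("activity values must be >= 0")
  if (length(object@suvScale) != 1L || !is.finite(object@suvScale) ||
      object@suvScale <= 0)
    return("suvScale must be a single positive number")
  TRUE
})

#' PhantomSpec: digital NEMA image-quality phantom specification
#'
#' Four hot spheres, coplanar on the central slice, inside an elliptical body
#' filled with a lower background concentration. Defaults reproduce the usual
#' fill scheme: spheres of 10/13/17/22 mm diameter at 13.2 kBq/mL with the
#' background at one quarter of that (4:1 hot contrast).
#'
#' @slot sphereDiameters numeric, sphere diameters (mm).
#' @slot sphereConcentration numeric, kBq/mL in the spheres.
#' @slot backgroundConcentration numeric, kBq/mL in the body background.
#' @slot bodySemiAxes numeric length 2, in-plane semi-axes (mm) of the body
#'   ellipse (extruded along z).
#' @slot sphereCenters numeric matrix (n x 2), in-plane sphere centers (mm),
#'   relative to the grid center; spheres sit on the central slice plane.
#' @export
setClass("PhantomSpec",
  representation(sphereDiameters = "numeric",
                 sphereConcentration = "numeric",
                 backgroundConcentration = "numeric",
                 bodySemiAxes = "numeric",
                 sphereCenters = "matrix"))

setValidity("PhantomSpec", function(object) {
  nd <- length(object@sphereDiameters)
  if (any(object@sphereDiameters <= 0)) return("sphere diameters must be > 0")
  if (nrow(object@sphereCenters) != nd || ncol(object@sphereCenters) != 2L)
    return("sphereCenters must be an n x 2 matrix matching sphereDiameters")
  if (object@backgroundConcentration < 0 || object@sphereConcentration < 0)
    return("concentrations must be >= 0")
  if (object@backgroundConcentration > 0 &&
      object@sphereConcentration / object@backgroundConcentration <= 1)
    return("hot spheres require sphereConcentration / backgroundConcentration > 1")
  if (length(object@bodySemiAxes) != 2L || any(object@bodySemiAxes <= 0))
    return("bodySemiAxes must be two positive numbers")
  r <- object@sphereDiameters / 2
  a <- object@bodySemiAxes[1]; b <- object@bodySemiAxes[2]
  for (j in seq_len(nd)) {
    cx <- object@sphereCenters[j, 1]; cy <- object@sphereCenters[j, 2]
    # conservative containment: center inside the ellipse shrunk by the radius
    if (a <= r[j] || b <= r[j] ||
        (cx / (a - r[j]))^2 + (cy / (b - r[j]))^2 > 1)
      return(sprintf("sphere %d extends outside the body outline", j))
  }
  if (nd > 1) {
    cc <- object@sphereCenters
    for (j in seq_len(nd - 1)) for (k in (j + 1):nd) {
      if (sqrt(sum((cc[j, ] - cc[k, ])^2)) < r[j] + r[k])
        return(sprintf("spheres %d and %d overlap", j, k))
    }
  }
  TRUE
})

#' LesionSpec: one synthetic focal lesion
#'
#' @slot center numeric length 3, lesion center (mm) relative to grid center.
#' @slot diameter numeric, true diameter (mm).
#' @slot suv numeric, lesion SUV; must exceed the body background SUV.
#' @slot tissue character, context tag: lung, bone, lymph_node or soft_tissue.
#' @export
setClass("LesionSpec",
  representation(center = "numeric", diameter = "numeric", suv = "numeric",
                 tissue = "character"),
  prototype(tissue = "soft_tissue"))

setValidity("LesionSpec", function(object) {
  if (length(object@center) != 3L) return("center must have length 3")
  if (object@diameter <= 0) return("diameter must be > 0")
  if (!object@tissue %in% c("lung", "bone", "lymph_node", "soft_tissue"))
    return("tissue must be one of lung, bone, lymph_node, soft_tissue")
  TRUE
})

#' PatientSpec: synthetic patient volume specification
#'
#' A torso-like elliptical body at a low background SUV, a uniform ellipsoidal
#' liver compartment, and spherical focal lesions. Carries the dosimetry needed
#' for SUV calibration: injected activity and body weight, with
#' suvScale = IA\[kBq\]/weight\[g\].
#'
#' @slot weightKg,heightM,injectedActivityMBq numeric patient dosimetry.
#' @slot bodySemiAxes numeric length 2, in-plane body ellipse semi-axes (mm).
#' @slot liverCenter numeric length 3, liver center (mm).
#' @slot liverSemiAxes numeric length 3, liver ellipsoid semi-axes (mm).
#' @slot liverSuv numeric, uniform liver SUV (default 5.96).
#' @slot backgroundSuv numeric, body background SUV.
#' @slot lesions list of [LesionSpec].
#' @slot voiDiameter numeric, diameter (mm) of the liver noise VOI whose
#'   placement region lesions must not invade.
#' @export
setClass("PatientSpec",
  representation(weightKg = "numeric", heightM = "numeric",
                 injectedActivityMBq = "numeric",
                 bodySemiAxes = "numeric",
                 liverCenter = "numeric", liverSemiAxes = "numeric",
                 liverSuv = "numeric", backgroundSuv = "numeric",
                 lesions = "list", voiDiameter = "numeric"),
  prototype(voiDiameter = 30))

setValidity("PatientSpec", function(object) {
  if (object@weightKg <= 0 || object@heightM <= 0 ||
      object@injectedActivityMBq <= 0)
    return("weight, height and injected activity must all be > 0")
  if (length(object@bodySemiAxes) != 2L || any(object@bodySemiAxes <= 0))
    return("bodySemiAxes must be two positive numbers")
  if (length(object@liverCenter) != 3L || length(object@liverSemiAxes) != 3L ||
      any(object@liverSemiAxes <= 0))
    return("liver geometry must be a 3-vector center and positive semi-axes")
  if (object@liverSuv <= object@backgroundSuv)
    return("liver SUV must exceed the background SUV")
  for (les in object@lesions) {
    if (!is(les, "LesionSpec")) return("lesions must be LesionSpec objects")
    validObject(les)
    if (les@suv <= object@backgroundSuv)
      return("lesion SUV must exceed the background SUV")
  }
  TRUE
})

#' ProjectionGeometry: 2D parallel-beam projection geometry
#'
#' Parallel-beam geometry applied slice-by-slice: `nAngles` view angles evenly
#' spaced over 180 degrees, `nBins` radial bins of width `binWidth` mm centered
#' on the rotation axis. The radial extent must cover the image-grid diagonal.
#'
#' @slot nAngles integer, number of projection angles over 180 degrees (>= 8).
#' @slot nBins integer, radial bins.
#' @slot binWidth numeric, radial bin width (mm).
#' @export
setClass("ProjectionGeometry",
  representation(nAngles = "integer", nBins = "integer", binWidth = "numeric"))

setValidity("ProjectionGeometry", function(object) {
  if (object@nAngles < 8L) return("nAngles must be >= 8")
  if (object@nBins < 1L) return("nBins must be >= 1")
  if (object@binWidth <= 0) return("binWidth must be > 0")
  TRUE
})

#' CountBudget: acquisition-duration-equivalent count budget
#'
#' Total expected counts for a Poisson acquisition, tagged with the
#' minutes-per-bed duration class (2 or 3) it emulates and the RNG seed used
#' for the draw.
#'
#' @slot durationClass numeric, 2 or 3 (minutes-per-bed equivalent).
#' @slot expectedTotalCounts numeric, expected total counts (> 0, or 0 for the
#'   degenerate empty acquisition).
#' @slot seed integer RNG seed.
#' @export
setClass("CountBudget",
  representation(durationClass = "numeric", expectedTotalCounts = "numeric",
                 seed = "integer"))

setValidity("CountBudget", function(object) {
  if (!object@durationClass %in% c(2, 3))
    return("durationClass must be 2 or 3")
  if (object@expectedTotalCounts < 0)
    return("expectedTotalCounts must be >= 0")
  TRUE
})

#' Sinogram: projection-domain data
#'
#' Per-(bin, angle, slice) projection values: either expected line integrals
#' (`kind = "expected"`, nonnegative reals) or Poisson counts
#' (`kind = "counts"`, nonnegative integers).
#'
#' @slot values numeric array (nBins x nAngles x nz).
#' @slot geometry a [ProjectionGeometry].
#' @slot kind character, `"expected"` or `"counts"`.
#' @slot meta list of provenance (budget, seed, duration class).
#' @export
setClass("Sinogram",
  representation(values = "array", geometry = "ProjectionGeometry",
                 kind = "character", meta = "list"),
  prototype(kind = "expected", meta = list()))

setValidity("Sinogram", function(object) {
  d <- dim(object@values)
  g <- object@geometry
  if (length(d) != 3L || d[1] != g@nBins || d[2] != g@nAngles)
    return("values must be an nBins x nAngles x nz array")
  if (!object@kind %in% c("expected", "counts"))
    return("kind must be 'expected' or 'counts'")
  if (any(object@values < 0)) return("sinogram values must be >= 0")
  if (object@kind == "counts" &&
      any(abs(object@values - round(object@values)) > 1e-9))
    return("counts sinogram must hold integer values")
  TRUE
})

#' OsemProtocol: standard OSEM reconstruction protocol
#'
#' Defaults follow the standard clinical protocol emulated here: 2 iterations,
#' 20 subsets, 3 mm Gaussian post-filter, with a 4 mm Gaussian resolution model
#' shared with the simulation.
#'
#' @slot iterations integer, full iterations (>= 1).
#' @slot subsets integer, ordered subsets; must divide the number of angles.
#' @slot postFilterFwhm numeric, Gaussian post-filter FWHM (mm); 0 disables.
#' @slot modelPsfFwhm numeric, FWHM (mm) of the Gaussian resolution model
#'   included in the reconstruction forward projector.
#' @export
setClass("OsemProtocol",
  representation(iterations = "integer", subsets = "integer",
                 postFilterFwhm = "numeric", modelPsfFwhm = "numeric"),
  prototype(iterations = 2L, subsets = 20L, postFilterFwhm = 3,
            modelPsfFwhm = 4))

setValidity("OsemProtocol", function(object) {
  if (object@iterations < 1L) return("iterations must be >= 1")
  if (object@subsets < 1L) return("subsets must be >= 1")
  if (object@postFilterFwhm < 0 || object@modelPsfFwhm < 0)
    return("filter FWHMs must be >= 0")
  TRUE
})

#' PemProtocol: one-step-late TV-penalized EM protocol
#'
#' Penalized EM with an epsilon-smoothed total-variation penalty incorporated
#' one-step-late in the EM denominator. The user-facing knob is the
#' penalization factor `beta` (grid 0.03-0.5); `kappa` is a global
#' penalty-scale constant calibrated once and then frozen;
#' `necReferenceCounts` sets the reference count level for the
#' sqrt(reference/actual) count-dependent penalty scaling, and
#' `sensitivityWeighting` switches the normalized local sensitivity weight.
#'
#' @slot beta numeric penalization factor (>= 0).
#' @slot iterations integer (default 10).
#' @slot subsets integer (default 20).
#' @slot tvEpsilonRel numeric, TV smoothing constant as a fraction of the mean
#'   nonzero initialization value.
#' @slot kappa numeric global penalty-scale calibration constant (> 0).
#' @slot necReferenceCounts numeric reference count level (> 0).
#' @slot sensitivityWeighting logical.
#' @slot stopTol numeric, relative L2 image-change stopping tolerance.
#' @slot modelPsfFwhm numeric, Gaussian resolution-model FWHM (mm).
#' @export
setClass("PemProtocol",
  representation(beta = "numeric", iterations = "integer", subsets = "integer",
                 tvEpsilonRel = "numeric", kappa = "numeric",
                 necReferenceCounts = "numeric",
                 sensitivityWeighting = "logical", stopTol = "numeric",
                 modelPsfFwhm = "numeric"),
  prototype(iterations = 2L, subsets = 20L, tvEpsilonRel = 1e-3,
            kappa = 0.8, necReferenceCounts = 4.8e6,
            sensitivityWeighting = TRUE, stopTol = 1e-4, modelPsfFwhm = 4))

setValidity("PemProtocol", function(object) {
  if (object@beta < 0) return("beta must be >= 0")
  if (object@iterations < 1L || object@subsets < 1L)
    return("iterations and subsets must be >= 1")
  if (object@tvEpsilonRel <= 0) return("tvEpsilonRel must be > 0")
  if (object@kappa <= 0) return("kappa must be > 0")
  if (object@necReferenceCounts <= 0)
    return("necReferenceCounts must be > 0")
  if (object@modelPsfFwhm < 0) return("modelPsfFwhm must be >= 0")
  TRUE
})

#' GroupLabel: reconstruction-arm label
#'
#' Compact label for one reconstruction arm in the conventional scheme:
#' `O2`/`O3` for OSEM at 2/3 minutes per bed, `HR{d}.{beta}` for the penalized
#' algorithm (e.g. `HR2.03` for beta 0.03 at 2 m/b, `HR3.5` for beta 0.5 at
#' 3 m/b). Labels round-trip uniquely to (algorithm, duration, beta).
#'
#' @slot label character.
#' @slot algorithm character, "OSEM" or "PEM".
#' @slot durationClass numeric, 2 or 3.
#' @slot beta numeric, penalization factor (NA for OSEM).
#' @export
setClass("GroupLabel",
  representation(label = "character", algorithm = "character",
                 durationClass = "numeric", beta = "numeric"),
  prototype(label = NA_character_, algorithm = NA_character_,
            durationClass = NA_real_, beta = NA_real_))

setValidity("GroupLabel", function(object) {
  if (is.na(object@label)) return(TRUE)  # empty placeholder allowed
  if (!object@algorithm %in% c("OSEM", "PEM"))
    return("algorithm must be OSEM or PEM")
  if (!object@durationClass %in% c(2, 3))
    return("durationClass must be 2 or 3")
  if (object@algorithm == "PEM" &&
      (is.na(object@beta) || object@beta < 0))
    return("PEM labels need beta >= 0")
  ok <- .formatGroupLabel(object@algorithm, object@durationClass, object@beta)
  if (!identical(ok, object@label))
    return(sprintf("label '%s' does not round-trip (expected '%s')",
                   object@label, ok))
  TRUE
})

#' ReconResult: one reconstructed volume with provenance
#'
#' @slot image the reconstructed [ActivityVolume] (nonnegative everywhere).
#' @slot protocol the protocol object used ([OsemProtocol] or [PemProtocol]).
#' @slot trace numeric, relative L2 image change per completed full iteration.
#' @slot label a [GroupLabel] (possibly the empty placeholder).
#' @export
setClass("ReconResult",
  representation(image = "ActivityVolume", protocol = "ANY",
                 trace = "numeric", label = "GroupLabel"))

setValidity("ReconResult", function(object) {
  if (any(object@image@values < 0))
    return("reconstructed image must be nonnegative")
  TRUE
})

#' RoiLayout: NEMA-style ROI layout for phantom evaluation
#'
#' One circular ROI per sphere, concentric with the true sphere center and
#' matched to the sphere diameter, plus a ring of circular background ROIs per
#' sphere size on the central slice. Background ROIs stay at least
#' `clearanceMm` edge-to-edge from every sphere and inside the body outline.
#'
#' @slot sphereRois data.frame: sphere, cx, cy, diameter (mm).
#' @slot backgroundRois data.frame: sphere, roi, cx, cy, diameter (mm).
#' @slot clearanceMm numeric, minimum sphere-to-ROI edge clearance (mm).
#' @export
setClass("RoiLayout",
  representation(sphereRois = "data.frame", backgroundRois = "data.frame",
                 clearanceMm = "numeric"),
  prototype(clearanceMm = 15))
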