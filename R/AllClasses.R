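#' @import methods
NULL

setClassUnion("dataframeOrNULL", c("data.frame", "NULL"))

# ---------------------------------------------------------------------------
# Phantom specification classes
# ---------------------------------------------------------------------------

#' OrganSpec: one organ (or tumour) of a digital phantom
#'
#' Describes a geometric primitive filled with a uniform activity
#' concentration that washes out mono-exponentially on top of physical decay.
#'
#' @slot name organ identifier (e.g. \code{"kidney_left"}).
#' @slot shape one of \code{"ellipsoid"}, \code{"sphere"}, \code{"box"}.
#' @slot center centre in mm, length 3 (x, y, z; 0 = grid corner).
#' @slot semiAxes semi-axes in mm, length 3 (for a sphere all equal; for a
#'   box, half-widths).
#' @slot density tissue density in g/mL.
#' @slot uptakeFraction fraction of the administered activity taken up at
#'   t = 0 (dimensionless, >= 0).
#' @slot bioHalfLife biological half-life in hours; \code{Inf} means physical
#'   decay only.
#' @slot isTumour logical flag; tumours get sphere-model dosimetry with
#'   partial-volume recovery.
#' @slot hostOrgan name of the organ a tumour sits inside, or
#'   \code{NA_character_}.
#' @seealso [organSpec()], [phantomSpec()], [buildPhantom()]
#' @export
setClass("OrganSpec",
  representation(name = "character", shape = "character", center = "numeric",
                 semiAxes = "numeric", density = "numeric",
                 uptakeFraction = "numeric", bioHalfLife = "numeric",
                 isTumour = "logical", hostOrgan = "character"),
  prototype(shape = "ellipsoid", density = 1.05, uptakeFraction = 0,
            bioHalfLife = Inf, isTumour = FALSE, hostOrgan = NA_character_))

setValidity("OrganSpec", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (!object@shape %in% c("ellipsoid", "sphere", "box"))
    msg <- c(msg, "shape must be ellipsoid, sphere or box")
  if (length(object@center) != 3L || anyNA(object@center))
    msg <- c(msg, "center must be numeric length 3")
  if (length(object@semiAxes) != 3L || any(object@semiAxes <= 0))
    msg <- c(msg, "semiAxes must be positive, length 3")
  if (object@density <= 0) msg <- c(msg, "density must be > 0")
  if (object@uptakeFraction < 0) msg <- c(msg, "uptakeFraction must be >= 0")
  if (object@bioHalfLife <= 0) msg <- c(msg, "bioHalfLife must be > 0 (Inf allowed)")
  if (length(msg)) msg else TRUE
})

#' Construct an OrganSpec
#'
#' @param name organ identifier.
#' @param shape \code{"ellipsoid"}, \code{"sphere"} or \code{"box"}.
#' @param center centre in mm (length 3).
#' @param semiAxes semi-axes / half-widths in mm (length 3, or length 1 for a
#'   sphere).
#' @param density tissue density g/mL.
#' @param uptakeFraction fraction of administered activity at t = 0.
#' @param bioHalfLife biological half-life in hours (\code{Inf} = physical
#'   decay only).
#' @param isTumour logical.
#' @param hostOrgan host organ name for tumours, or \code{NA}.
#' @return an [OrganSpec-class] object.
#' @examples
#' organSpec("kidney_left", "ellipsoid", c(60, 80, 100), c(30, 20, 50),
#'           density = 1.05, uptakeFraction = 0.02, bioHalfLife = 70)
#' @export
organSpec <- function(name, shape = "ellipsoid", center, semiAxes,
                      density = 1.05, uptakeFraction = 0, bioHalfLife = Inf,
                      isTumour = FALSE, hostOrgan = NA_character_) {
  if (shape == "sphere" && length(semiAxes) == 1L) semiAxes <- rep(semiAxes, 3L)
  new("OrganSpec", name = name, shape = shape, center = as.numeric(center),
      semiAxes = as.numeric(semiAxes), density = density,
      uptakeFraction = uptakeFraction, bioHalfLife = bioHalfLife,
      isTumour = isTumour, hostOrgan = hostOrgan)
}

#' PhantomSpec: geometry and kinetics of a whole digital phantom
#'
#' @slot dim grid shape (nx, ny, nz) in voxels.
#' @slot voxelSize voxel edge lengths in mm (length 3).
#' @slot organs list of [OrganSpec-class].
#' @slot bodyShape \code{"box"} or \code{"ellipsoid"}; the body carries the
#'   soft-tissue attenuation and the background activity.
#' @slot bodyCenter,bodySemiAxes body extent in mm.
#' @slot backgroundUptake uptake fraction of the remainder body tissue.
#' @slot backgroundHalfLife biological half-life (h) of the remainder.
#' @slot muSoft,muLung linear attenuation coefficients (cm^-1) at 208 keV for
#'   soft tissue and lung.
#' @seealso [phantomSpec()], [buildPhantom()]
#' @export
setClass("PhantomSpec",
  representation(dim = "integer", voxelSize = "numeric", organs = "list",
                 bodyShape = "character", bodyCenter = "numeric",
                 bodySemiAxes = "numeric", backgroundUptake = "numeric",
                 backgroundHalfLife = "numeric", muSoft = "numeric",
                 muLung = "numeric"),
  prototype(bodyShape = "box", backgroundUptake = 0, backgroundHalfLife = Inf,
            muSoft = 0.137, muLung = 0.04))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@dim) != 3L || any(object@dim < 4L))
    msg <- c(msg, "dim must be three voxel counts >= 4")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be positive, length 3")
  if (!all(vapply(object@organs, is, logical(1), class2 = "OrganSpec")))
    msg <- c(msg, "organs must all be OrganSpec")
  nm <- vapply(object@organs, slot, character(1), name = "name")
  if (anyDuplicated(nm)) msg <- c(msg, "organ names must be unique")
  fsum <- sum(vapply(object@organs, slot, numeric(1), name = "uptakeFraction")) +
    object@backgroundUptake
  if (fsum > 1 + 1e-9)
    msg <- c(msg, "total uptake fraction (organs + background) must be <= 1")
  if (object@backgroundUptake < 0) msg <- c(msg, "backgroundUptake must be >= 0")
  if (object@muSoft < 0 || object@muLung < 0)
    msg <- c(msg, "attenuation coefficients must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' @param dim grid shape (nx, ny, nz) in voxels.
#' @param voxelSize voxel size in mm (scalar or length 3).
#' @param organs list of [OrganSpec-class].
#' @param bodyShape \code{"box"} or \code{"ellipsoid"}.
#' @param bodyCenter,bodySemiAxes body placement in mm; default a body filling
#'   90\% of the grid.
#' @param backgroundUptake uptake fraction of remainder body tissue.
#' @param backgroundHalfLife biological half-life (h) of the remainder.
#' @param muSoft,muLung attenuation coefficients cm^-1 at 208 keV.
#' @return a [PhantomSpec-class] object.
#' @export
phantomSpec <- function(dim, voxelSize, organs = list(), bodyShape = "box",
                        bodyCenter = NULL, bodySemiAxes = NULL,
                        backgroundUptake = 0, backgroundHalfLife = Inf,
                        muSoft = 0.137, muLung = 0.04) {
  dim <- as.integer(dim)
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  extent <- dim * voxelSize
  if (is.null(bodyCenter)) bodyCenter <- extent / 2
  if (is.null(bodySemiAxes)) bodySemiAxes <- 0.45 * extent
  new("PhantomSpec", dim = dim, voxelSize = as.numeric(voxelSize),
      organs = organs, bodyShape = bodyShape,
      bodyCenter = as.numeric(bodyCenter),
      bodySemiAxes = as.numeric(bodySemiAxes),
      backgroundUptake = backgroundUptake,
      backgroundHalfLife = backgroundHalfLife, muSoft = muSoft,
      muLung = muLung)
}

#' AcquisitionSpec: imaging protocol parameters
#'
#' @slot timePoints planar imaging time points, hours post injection,
#'   strictly increasing, >= 2 of them. Default \code{c(4, 24, 48, 72, 168)}.
#' @slot spectTimes subset of \code{timePoints} at which SPECT volumes are
#'   acquired.
#' @slot physicalHalfLife physical half-life in hours (default 159.528 h =
#'   6.647 d for 177Lu).
#' @slot planarSensitivity planar system sensitivity, counts s^-1 MBq^-1.
#' @slot planarDuration planar acquisition duration, s.
#' @slot spectFwhm,planarFwhm Gaussian PSF FWHM in mm for SPECT volumes and
#'   planar images.
#' @slot noise logical; Poisson noise on planar counts.
#' @slot spectNoiseSd relative Gaussian noise on SPECT voxels (0 = off).
#' @slot seed integer RNG seed for the simulation.
#' @seealso [acquisitionSpec()], [simulateStudy()]
#' @export
setClass("AcquisitionSpec",
  representation(timePoints = "numeric", spectTimes = "numeric",
                 physicalHalfLife = "numeric", planarSensitivity = "numeric",
                 planarDuration = "numeric", spectFwhm = "numeric",
                 planarFwhm = "numeric", noise = "logical",
                 spectNoiseSd = "numeric", seed = "integer"),
  prototype(timePoints = c(4, 24, 48, 72, 168), physicalHalfLife = 159.528,
            planarSensitivity = 10, planarDuration = 300, spectFwhm = 0,
            planarFwhm = 0, noise = FALSE, spectNoiseSd = 0, seed = 1L))

setValidity("AcquisitionSpec", function(object) {
  msg <- character()
  tp <- object@timePoints
  if (length(tp) < 2L || any(diff(tp) <= 0) || any(tp < 0))
    msg <- c(msg, "timePoints must be >= 2 non-negative, strictly increasing values")
  if (!all(object@spectTimes %in% tp))
    msg <- c(msg, "spectTimes must be a subset of timePoints")
  if (object@physicalHalfLife <= 0) msg <- c(msg, "physicalHalfLife must be > 0")
  if (object@spectFwhm < 0 || object@planarFwhm < 0)
    msg <- c(msg, "PSF FWHM must be >= 0")
  if (object@planarSensitivity <= 0 || object@planarDuration <= 0)
    msg <- c(msg, "planar sensitivity and duration must be > 0")
  if (object@spectNoiseSd < 0) msg <- c(msg, "spectNoiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an AcquisitionSpec
#'
#' @param timePoints planar time points (h p.i.).
#' @param spectTimes SPECT time points (default: all planar time points).
#' @param physicalHalfLife physical half-life, hours.
#' @param planarSensitivity counts s^-1 MBq^-1.
#' @param planarDuration seconds.
#' @param spectFwhm,planarFwhm Gaussian PSF FWHM, mm.
#' @param noise Poisson noise on planar counts?
#' @param spectNoiseSd relative Gaussian noise on SPECT voxels.
#' @param seed integer seed.
#' @return an [AcquisitionSpec-class].
#' @export
acquisitionSpec <- function(timePoints = c(4, 24, 48, 72, 168),
                            spectTimes = timePoints,
                            physicalHalfLife = 159.528,
                            planarSensitivity = 10, planarDuration = 300,
                            spectFwhm = 0, planarFwhm = 0, noise = FALSE,
                            spectNoiseSd = 0, seed = 1L) {
  new("AcquisitionSpec", timePoints = as.numeric(timePoints),
      spectTimes = as.numeric(spectTimes),
      physicalHalfLife = physicalHalfLife,
      planarSensitivity = planarSensitivity,
      planarDuration = planarDuration, spectFwhm = spectFwhm,
      planarFwhm = planarFwhm, noise = noise, spectNoiseSd = spectNoiseSd,
      seed = as.integer(seed))
}

#' AdministrationRecord: the injected therapy activity
#'
#' @slot activityGBq administered activity in GBq at \code{time0}.
#' @slot time0 administration time (hours; 0 by convention).
#' @export
setClass("AdministrationRecord",
  representation(activityGBq = "numeric", time0 = "numeric"),
  prototype(time0 = 0))

setValidity("AdministrationRecord", function(object) {
  if (length(object@activityGBq) != 1L || object@activityGBq <= 0)
    "activityGBq must be a single positive number" else TRUE
})

#' @rdname AdministrationRecord-class
#' @param activityGBq administered activity, GBq.
#' @param time0 administration time, h (default 0).
#' @return an \code{AdministrationRecord}.
#' @examples administrationRecord(7.2)
#' @export
administrationRecord <- function(activityGBq, time0 = 0)
  new("AdministrationRecord", activityGBq = activityGBq, time0 = time0)

#' CalibrationStandard: the co-scanned 177Lu syringe
#'
#' A syringe of known activity placed below the feet of the patient in every
#' planar acquisition; its counts calibrate the planar sensitivity.
#'
#' @slot activityMBq nominal activity (MBq) at \code{refTimeH}.
#' @slot refTimeH reference time of the nominal activity, hours on the study
#'   clock (0 = administration).
#' @slot volumeML physical volume, mL.
#' @slot location integer vector (x1, x2, z1, z2): the pixel block the syringe
#'   occupies in the planar field of view.
#' @slot durationS acquisition duration used when measuring the standard, s.
#' @export
setClass("CalibrationStandard",
  representation(activityMBq = "numeric", refTimeH = "numeric",
                 volumeML = "numeric", location = "integer",
                 durationS = "numeric"),
  prototype(refTimeH = 0, volumeML = 50, durationS = 300))

setValidity("CalibrationStandard", function(object) {
  msg <- character()
  if (object@activityMBq <= 0) msg <- c(msg, "activityMBq must be > 0")
  if (object@volumeML <= 0) msg <- c(msg, "volumeML must be > 0")
  if (length(object@location) != 4L)
    msg <- c(msg, "location must be (x1, x2, z1, z2)")
  if (length(msg)) msg else TRUE
})

#' @rdname CalibrationStandard-class
#' @param activityMBq nominal activity, MBq.
#' @param refTimeH reference time, h.
#' @param volumeML syringe volume, mL.
#' @param location pixel block (x1, x2, z1, z2) in the planar image.
#' @param durationS acquisition duration, s.
#' @return a \code{CalibrationStandard}.
#' @examples calibrationStandard(196, location = c(2, 4, 2, 4))
#' @export
calibrationStandard <- function(activityMBq = 196, refTimeH = 0,
                                volumeML = 50, location = c(2L, 4L, 2L, 4L),
                                durationS = 300) {
  new("CalibrationStandard", activityMBq = activityMBq, refTimeH = refTimeH,
      volumeML = volumeML, location = as.integer(location),
      durationS = durationS)
}

# ---------------------------------------------------------------------------
# Built phantom and study containers
# ---------------------------------------------------------------------------

#' VoxelPhantom: a rasterised phantom
#'
#' Produced by [buildPhantom()]: per-organ boolean masks (mutually disjoint in
#' 3D), a body mask, and density (g/mL) and attenuation (cm^-1) volumes on the
#' same grid.
#'
#' @slot spec the generating [PhantomSpec-class].
#' @slot masks named list of logical 3D arrays, one per organ.
#' @slot body logical 3D array: the body outline.
#' @slot density numeric 3D array, g/mL.
#' @slot attenuation numeric 3D array, cm^-1 at 208 keV.
#' @export
setClass("VoxelPhantom",
  representation(spec = "PhantomSpec", masks = "list", body = "array",
                 density = "array", attenuation = "array"))

setValidity("VoxelPhantom", function(object) {
  msg <- character()
  d <- dim(object@body)
  for (m in object@masks)
    if (!identical(dim(m), d)) msg <- c(msg, "all masks must share the body grid")
  if (length(object@masks) >= 2L) {
    tot <- Reduce(`+`, lapply(object@masks, function(m) m * 1L))
    if (max(tot) > 1L) msg <- c(msg, "organ masks must be disjoint in 3D")
  }
  if (length(msg)) msg else TRUE
})

#' StudyDataset: one simulated (or imported) patient-equivalent study
#'
#' The container every scenario consumes: per-time-point anterior/posterior
#' planar count images, quantitative SPECT-like activity volumes at a subset
#' of time points, the voxel phantom (masks, density, attenuation), the
#' administration and calibration records, and (for simulated studies) a
#' ground-truth kinetics record.
#'
#' @slot timesH planar time points, h p.i.
#' @slot anterior,posterior lists of count matrices (x along rows, z along
#'   columns), one per time point. Posterior images are stored as acquired by
#'   a rear detector, i.e. left-right mirrored relative to the anterior frame.
#' @slot spectTimesH SPECT time points (subset of \code{timesH}).
#' @slot spect named list (names = time in h) of activity volumes, MBq/voxel.
#' @slot phantom a [VoxelPhantom-class].
#' @slot admin an [AdministrationRecord-class].
#' @slot calibration a [CalibrationStandard-class].
#' @slot acquisition the [AcquisitionSpec-class] used.
#' @slot truth data.frame (organ, f, lambda_eff_per_h, tau_h, mass_g,
#'   dose_Gy, dpa_Gy_per_GBq) or NULL for imported data.
#' @seealso [simulateStudy()], [readStudy()], [writeStudy()]
#' @export
setClass("StudyDataset",
  representation(timesH = "numeric", anterior = "list", posterior = "list",
                 spectTimesH = "numeric", spect = "list",
                 phantom = "VoxelPhantom", admin = "AdministrationRecord",
                 calibration = "CalibrationStandard",
                 acquisition = "AcquisitionSpec", truth = "dataframeOrNULL"))

setValidity("StudyDataset", function(object) {
  msg <- character()
  nt <- length(object@timesH)
  if (nt < 2L || any(diff(object@timesH) <= 0))
    msg <- c(msg, "timesH must be >= 2 strictly increasing time points")
  if (length(object@anterior) != nt || length(object@posterior) != nt)
    msg <- c(msg, "one anterior and one posterior image per time point required")
  if (!all(object@spectTimesH %in% object@timesH))
    msg <- c(msg, "spectTimesH must be a subset of timesH")
  if (length(object@spect) != length(object@spectTimesH))
    msg <- c(msg, "one SPECT volume per SPECT time point required")
  pd <- dim(object@phantom@body)[c(1L, 3L)]
  for (img in c(object@anterior, object@posterior))
    if (!identical(dim(img), pd))
      msg <- c(msg, "planar images must match the phantom (x, z) grid")
  for (v in object@spect)
    if (!identical(dim(v), dim(object@phantom@body)))
      msg <- c(msg, "SPECT volumes must match the phantom grid")
  if (any(vapply(c(object@anterior, object@posterior),
                 function(img) any(img < 0), logical(1))))
    msg <- c(msg, "planar counts must be >= 0")
  if (length(msg)) unique(msg) else TRUE
})

# ---------------------------------------------------------------------------
# Kinetics / quantification result classes
# ---------------------------------------------------------------------------

#' TimeActivityCurve: measured organ activity over time
#'
#' @slot organ organ identifier.
#' @slot timesH time points, hours p.i., strictly increasing, >= 2.
#' @slot activitiesMBq measured activities, MBq, >= 0.
#' @slot method quantification method tag: \code{"planar"}, \code{"spect"} or
#'   \code{"hybrid"}.
#' @seealso [timeActivityCurve()], [fitMonoexp()]
#' @export
setClass("TimeActivityCurve",
  representation(organ = "character", timesH = "numeric",
                 activitiesMBq = "numeric", method = "character"),
  prototype(method = "spect"))

setValidity("TimeActivityCurve", function(object) {
  msg <- character()
  if (length(object@timesH) < 2L || any(diff(object@timesH) <= 0))
    msg <- c(msg, "timesH must be >= 2 strictly increasing values")
  if (length(object@activitiesMBq) != length(object@timesH))
    msg <- c(msg, "activitiesMBq must match timesH in length")
  if (any(object@activitiesMBq < 0)) msg <- c(msg, "activities must be >= 0")
  if (!object@method %in% c("planar", "spect", "hybrid"))
    msg <- c(msg, "method must be planar, spect or hybrid")
  if (length(msg)) msg else TRUE
})

#' @rdname TimeActivityCurve-class
#' @param organ organ identifier.
#' @param timesH time points (h).
#' @param activitiesMBq activities (MBq).
#' @param method method tag.
#' @return a \code{TimeActivityCurve}.
#' @examples timeActivityCurve("kidney", c(4, 24, 72), c(250, 180, 90))
#' @export
timeActivityCurve <- function(organ, timesH, activitiesMBq, method = "spect")
  new("TimeActivityCurve", organ = organ, timesH = as.numeric(timesH),
      activitiesMBq = as.numeric(activitiesMBq), method = method)

#' FitResult: a mono-exponential time-activity fit
#'
#' @slot organ organ identifier.
#' @slot A0 fitted amplitude at t = 0, MBq.
#' @slot lambda fitted effective decay constant, h^-1.
#' @slot rss residual sum of squares (MBq^2).
#' @slot r2 coefficient of determination.
#' @slot converged logical.
#' @slot method quantification method tag.
#' @seealso [fitMonoexp()], [residenceTime()]
#' @export
setClass("FitResult",
  representation(organ = "character", A0 = "numeric", lambda = "numeric",
                 rss = "numeric", r2 = "numeric", converged = "logical",
                 method = "character"),
  prototype(converged = TRUE, method = "spect"))

setValidity("FitResult", function(object) {
  msg <- character()
  if (object@A0 <= 0) msg <- c(msg, "A0 must be > 0")
  if (object@lambda <= 0) msg <- c(msg, "lambda must be > 0 for accepted fits")
  if (length(msg)) msg else TRUE
})

#' ROI2D: a planar region of interest with its background band
#'
#' @slot organ organ identifier.
#' @slot mask logical matrix on the planar (x, z) grid; non-empty.
#' @slot background logical matrix, disjoint from \code{mask}; the
#'   thickness-weighted background band placed next to the organ.
#' @export
setClass("ROI2D",
  representation(organ = "character", mask = "matrix", background = "matrix"))

setValidity("ROI2D", function(object) {
  msg <- character()
  if (!any(object@mask)) msg <- c(msg, "ROI mask must be non-empty")
  if (!identical(dim(object@mask), dim(object@background)))
    msg <- c(msg, "background mask must share the ROI grid")
  else if (any(object@mask & object@background))
    msg <- c(msg, "background mask must be disjoint from the organ ROI")
  if (length(msg)) msg else TRUE
})

#' VOI3D: a 3D volume of interest
#'
#' @slot organ organ identifier.
#' @slot mask logical 3D array; non-empty.
#' @export
setClass("VOI3D", representation(organ = "character", mask = "array"))

setValidity("VOI3D", function(object) {
  if (!any(object@mask)) "VOI mask must be non-empty" else TRUE
})

#' BackgroundCorrectionSpec: organ/body thickness and the weighting factor
#'
#' The planar background subtraction weights the background band's count rate
#' by \code{wf = 1 - dOrgan/dBody}, where both extents are measured in the
#' anterior-posterior direction (from CT in the clinic; from the phantom masks
#' here).
#'
#' @slot dOrganCm organ anterior-posterior extent, cm.
#' @slot dBodyCm body anterior-posterior extent, cm.
#' @slot wf the weighting factor, \code{1 - dOrganCm/dBodyCm}.
#' @seealso [backgroundWeighting()], [correctBackground()]
#' @export
setClass("BackgroundCorrectionSpec",
  representation(dOrganCm = "numeric", dBodyCm = "numeric", wf = "numeric"))

setValidity("BackgroundCorrectionSpec", function(object) {
  msg <- character()
  if (object@dBodyCm <= 0) msg <- c(msg, "dBodyCm must be > 0")
  if (object@dOrganCm < 0 || object@dOrganCm > object@dBodyCm)
    msg <- c(msg, "need 0 <= dOrganCm <= dBodyCm")
  if (abs(object@wf - (1 - object@dOrganCm / object@dBodyCm)) > 1e-9)
    msg <- c(msg, "wf must equal 1 - dOrganCm/dBodyCm")
  if (length(msg)) msg else TRUE
})

#' RecoveryModel: sphere recovery coefficients for a Gaussian PSF
#'
#' @slot fwhmMm PSF full width at half maximum, mm.
#' @seealso [recoveryCoefficient()]
#' @export
setClass("RecoveryModel", representation(fwhmMm = "numeric"))

setValidity("RecoveryModel", function(object) {
  if (object@fwhmMm < 0) "fwhmMm must be >= 0" else TRUE
})

#' @rdname RecoveryModel-class
#' @param fwhmMm PSF FWHM, mm.
#' @return a \code{RecoveryModel}.
#' @export
recoveryModel <- function(fwhmMm) new("RecoveryModel", fwhmMm = fwhmMm)

#' DoseFactorTable: MIRD S-values per (target, source) pair
#'
#' Absorbed dose in a target per unit cumulated activity in a source, in
#' Gy per (GBq h), tabulated at a reference source mass. The default table
#' built by [defaultDoseFactorTable()] is a declared local electron-deposition
#' approximation (diagonal only); externally computed phantom S-values can be
#' loaded from CSV to add photon cross-dose.
#'
#' @slot entries data.frame with columns \code{target}, \code{source},
#'   \code{S_Gy_per_GBq_h}, \code{ref_mass_g}.
#' @seealso [defaultDoseFactorTable()], [readDoseFactorTable()], [organDose()]
#' @export
setClass("DoseFactorTable", representation(entries = "data.frame"))

setValidity("DoseFactorTable", function(object) {
  e <- object@entries
  need <- c("target", "source", "S_Gy_per_GBq_h", "ref_mass_g")
  if (!all(need %in% names(e)))
    return(paste("entries needs columns:", paste(need, collapse = ", ")))
  msg <- character()
  if (any(e$S_Gy_per_GBq_h < 0)) msg <- c(msg, "S-values must be >= 0")
  diagS <- e$S_Gy_per_GBq_h[e$target == e$source]
  if (any(diagS <= 0)) msg <- c(msg, "diagonal S-values must be > 0")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Scenario result classes
# ---------------------------------------------------------------------------

#' ScenarioResult: one dosimetry workflow applied to one study
#'
#' @slot scenario \code{"multi_spect"}, \code{"planar"} or \code{"hybrid"}.
#' @slot tacs named list of [TimeActivityCurve-class], one per organ.
#' @slot fits named list of [FitResult-class], one per organ.
#' @slot doses data.frame: organ, scenario, tau_h, mass_g, dose_Gy,
#'   dpa_Gy_per_GBq, is_tumour, flags.
#' @seealso [runMultiSpect()], [runPlanar()], [runHybrid()]
#' @export
setClass("ScenarioResult",
  representation(scenario = "character", tacs = "list", fits = "list",
                 doses = "data.frame"))

setValidity("ScenarioResult", function(object) {
  msg <- character()
  if (!object@scenario %in% c("multi_spect", "planar", "hybrid"))
    msg <- c(msg, "scenario must be multi_spect, planar or hybrid")
  if (anyDuplicated(object@doses$organ))
    msg <- c(msg, "every organ must appear exactly once")
  if (length(msg)) msg else TRUE
})

#' ScenarioComparison: paired dose comparison across the three scenarios
#'
#' @slot doses long data.frame: study, organ, scenario, dpa_Gy_per_GBq.
#' @slot friedman data.frame: organ, statistic, df, p_value.
#' @slot wilcoxon data.frame: organ, comparison, statistic, p_value
#'   (pairwise vs the multi-SPECT-CT scenario).
#' @slot ratios data.frame: organ, median per scenario, hybrid/multi and
#'   planar/multi median ratios (full precision plus one-decimal report
#'   rounding).
#' @seealso [compareScenarios()], [medianRatios()]
#' @export
setClass("ScenarioComparison",
  representation(doses = "data.frame", friedman = "data.frame",
                 wilcoxon = "data.frame", ratios = "data.frame"))

#' ObserverAgreementResult: inter-observer concordance on extracted counts
#'
#' @slot W Kendall's coefficient of concordance (tie-corrected), in [0, 1].
#' @slot pChisq chi-square approximation p-value.
#' @slot pPermutation seeded permutation p-value (NA if not computed).
#' @slot nObservers,nItems dimensions of the rating matrix.
#' @seealso [kendallsW()], [simulateObserverStudy()]
#' @export
setClass("ObserverAgreementResult",
  representation(W = "numeric", pChisq = "numeric", pPermutation = "numeric",
                 nObservers = "integer", nItems = "integer"))

setValidity("ObserverAgreementResult", function(object) {
  if (object@W < -1e-9 || object@W > 1 + 1e-9)
    "W must lie in [0, 1]" else TRUE
})
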