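# Quantification: conjugate-view planar activities with thickness-weighted
# background correction, SPECT VOI activities, projection-overlap handling,
# hybrid rescaling, and sphere recovery coefficients for the partial-volume
# correction of tumours.

#' Geometric-mean (conjugate-view) image
#'
#' Combines an anterior and a posterior planar image pixelwise as
#' \code{sqrt(a * p)}. Because the posterior detector views the patient from
#' behind, the posterior image as acquired is left-right mirrored; it is
#' flipped back onto the anterior frame before combination (disable with
#' \code{mirrorPosterior = FALSE} for images already in a common frame).
#'
#' @param anterior,posterior count matrices of equal shape, counts >= 0.
#' @param mirrorPosterior flip the posterior image along x first?
#' @return the geometric-mean image (same shape).
#' @examples
#' geometricMean(matrix(100, 2, 2), matrix(400, 2, 2),
#'               mirrorPosterior = FALSE)   # all 200
#' @export
geometricMean <- function(anterior, posterior, mirrorPosterior = TRUE) {
  if (!identical(dim(anterior), dim(posterior)))
    stop("anterior and posterior images must have the same shape")
  if (any(anterior < 0) || any(posterior < 0))
    stop("counts must be >= 0")
  if (mirrorPosterior)
    posterior <- posterior[rev(seq_len(nrow(posterior))), , drop = FALSE]
  # sqrt(a) * sqrt(p) rather than sqrt(a * p): integer count images would
  # overflow in the product
  sqrt(anterior) * sqrt(posterior)
}

#' Background weighting factor from organ and body thickness
#'
#' \code{wf = 1 - dOrgan/dBody}: the fraction of the body column next to an
#' organ that the organ itself does not occupy, used to weight the
#' background-band count rate before subtraction.
#'
#' @param dOrganCm organ extent in the anterior-posterior direction, cm.
#' @param dBodyCm body extent in the same direction, cm (> 0, >= dOrganCm).
#' @return the weighting factor in [0, 1].
#' @examples
#' backgroundWeighting(4.5, 25)   # 0.82
#' @export
backgroundWeighting <- function(dOrganCm, dBodyCm) {
  if (dBodyCm <= 0) stop("dBodyCm must be > 0")
  if (dOrganCm < 0 || dOrganCm > dBodyCm)
    stop("need 0 <= dOrganCm <= dBodyCm")
  1 - dOrganCm / dBodyCm
}

#' Build a BackgroundCorrectionSpec from thickness estimates
#'
#' @param dOrganCm,dBodyCm anterior-posterior extents, cm.
#' @return a [BackgroundCorrectionSpec-class].
#' @export
backgroundCorrectionSpec <- function(dOrganCm, dBodyCm)
  new("BackgroundCorrectionSpec", dOrganCm = dOrganCm, dBodyCm = dBodyCm,
      wf = backgroundWeighting(dOrganCm, dBodyCm))

#' Thickness-based background spec from phantom masks
#'
#' Computes the organ and body anterior-posterior extents the way the clinic
#' reads them off CT: mean chord length along y over the organ's projected
#' footprint (organ voxels x voxel depth / footprint pixels), and the mean
#' body thickness over the same footprint.
#'
#' @param phantom a [VoxelPhantom-class].
#' @param organ organ name.
#' @return a [BackgroundCorrectionSpec-class].
#' @export
thicknessFromMasks <- function(phantom, organ) {
  m <- phantom@masks[[organ]]
  if (is.null(m)) stop(sprintf("no mask for organ '%s'", organ))
  dyCm <- phantom@spec@voxelSize[2L] / 10
  foot <- apply(m, c(1L, 3L), any)
  dOrgan <- sum(m) * dyCm / sum(foot)
  bodyDepth <- apply(phantom@body, c(1L, 3L), sum) * dyCm
  dBody <- mean(bodyDepth[foot])
  backgroundCorrectionSpec(min(dOrgan, dBody), dBody)
}

#' Weighted background subtraction of ROI counts
#'
#' Subtracts \code{wf} times the per-pixel background rate, scaled to the
#' organ ROI size, from the organ ROI counts:
#' \code{organCounts - wf * (bgCounts/bgPixels) * organPixels}. Negative
#' results are floored at zero and flagged, never dropped silently.
#'
#' @param organCounts,organPixels ROI counts and pixel count.
#' @param bgCounts,bgPixels background band counts and pixel count.
#' @param wf weighting factor from [backgroundWeighting()].
#' @return list with \code{counts} (corrected, >= 0) and \code{floored}
#'   (logical).
#' @examples
#' correctBackground(1000, 50, 500, 50, 0.8)$counts   # 600
#' @export
correctBackground <- function(organCounts, organPixels, bgCounts, bgPixels,
                              wf) {
  if (organPixels <= 0 || bgPixels <= 0) stop("pixel counts must be > 0")
  if (organCounts < 0 || bgCounts < 0) stop("counts must be >= 0")
  corrected <- organCounts - wf * (bgCounts / bgPixels) * organPixels
  list(counts = max(corrected, 0), floored = corrected < 0)
}

#' Planar system sensitivity from the calibration standard
#'
#' \code{(counts/duration) / activity}, with the standard's nominal activity
#' decay-corrected from its reference time to the scan time.
#'
#' @param counts counts extracted over the standard (> 0).
#' @param durationS acquisition duration, s.
#' @param standard a [CalibrationStandard-class].
#' @param scanTimeH scan time on the study clock, h.
#' @param physicalHalfLife physical half-life, h.
#' @return sensitivity in counts s^-1 MBq^-1.
#' @examples
#' std <- calibrationStandard(196)
#' sensitivityFromStandard(19600, 100, std, scanTimeH = 0)   # 1 cps/MBq
#' @export
sensitivityFromStandard <- function(counts, durationS, standard,
                                    scanTimeH = standard@refTimeH,
                                    physicalHalfLife = 159.528) {
  if (counts <= 0)
    stop("no counts over the calibration standard (standard missing from the field of view?)")
  if (durationS <= 0) stop("duration must be > 0")
  act <- standard@activityMBq *
    exp(-log(2) / physicalHalfLife * (scanTimeH - standard@refTimeH))
  (counts / durationS) / act
}

#' Organ activity from a geometric-mean planar image
#'
#' Background-corrected ROI counts converted to a count rate and then to
#' activity through the planar sensitivity. Faithful to the planar workflow,
#' no attenuation correction is applied; with attenuation present this
#' estimate is systematically biased, which is the mechanism separating the
#' planar scenario from the SPECT-based ones.
#'
#' @param gmImage geometric-mean count image.
#' @param roi an [ROI2D-class] (organ mask + background band).
#' @param wf background weighting factor.
#' @param sensitivity planar sensitivity, counts s^-1 MBq^-1.
#' @param durationS acquisition duration, s.
#' @return list: \code{activityMBq}, \code{floored}.
#' @export
planarOrganActivity <- function(gmImage, roi, wf, sensitivity, durationS) {
  validObject(roi)
  if (!identical(dim(gmImage), dim(roi@mask)))
    stop("ROI grid does not match the image")
  oc <- sum(gmImage[roi@mask])
  bc <- sum(gmImage[roi@background])
  corr <- correctBackground(oc, sum(roi@mask), bc, sum(roi@background), wf)
  list(activityMBq = corr$counts / durationS / sensitivity,
       floored = corr$floored)
}

#' SPECT VOI activity
#'
#' Sum of voxel activities inside the VOI times the SPECT calibration
#' factor. Simulated volumes are already quantitative, so the factor defaults
#' to 1, but the code path exists because clinical systems require a manually
#' entered sensitivity factor.
#'
#' @param spectVol activity volume, MBq/voxel.
#' @param voi a [VOI3D-class] or logical array.
#' @param calibrationFactor multiplicative SPECT calibration factor.
#' @return activity, MBq.
#' @export
voiActivity <- function(spectVol, voi, calibrationFactor = 1) {
  mask <- if (is(voi, "VOI3D")) voi@mask else voi
  if (!any(mask)) stop("empty VOI")
  if (!identical(dim(spectVol), dim(mask)))
    stop("VOI grid does not match the volume")
  sum(spectVol[mask]) * calibrationFactor
}

#' Project a 3D VOI to a 2D ROI mask
#'
#' Union of the mask's columns along the projection (anterior-posterior)
#' axis.
#'
#' @param voi a [VOI3D-class] or logical 3D array.
#' @param axis projection axis (2 = y, the package convention).
#' @return logical matrix.
#' @export
projectVoi <- function(voi, axis = 2L) {
  mask <- if (is(voi, "VOI3D")) voi@mask else voi
  keep <- setdiff(seq_along(dim(mask)), axis)
  apply(mask, keep, any)
}

#' Remove projection overlaps and compute substitution factors
#'
#' When disjoint 3D VOIs overlap in 2D projection, the overlapping pixels are
#' excluded from every organ's 2D mask and the measured quantity from the
#' residual region is scaled up by \code{V_total/V_residual}, where the
#' volumes count 3D voxels whose projected pixel survives. The substitution
#' assumes uniform activity concentration within the organ (exact in that
#' case; a hot spot inside the removed part breaks it, which is a documented
#' limitation of the workflow).
#'
#' @param vois named list of [VOI3D-class] or logical 3D arrays.
#' @param axis projection axis.
#' @return named list per organ: \code{mask2d} (residual 2D mask),
#'   \code{factor} (>= 1), \code{voxelsTotal}, \code{voxelsResidual}.
#' @section Errors: an organ whose projection is fully claimed by overlaps
#'   (empty residual) raises an error naming it.
#' @export
removeOverlapAndSubstitute <- function(vois, axis = 2L) {
  if (!length(vois)) stop("need at least one VOI")
  masks <- lapply(vois, function(v) if (is(v, "VOI3D")) v@mask else v)
  proj <- lapply(masks, projectVoi, axis = axis)
  claimed <- Reduce(`+`, lapply(proj, function(m) m * 1L))
  overlap <- claimed >= 2L
  out <- vector("list", length(masks))
  names(out) <- names(masks)
  keepAxes <- setdiff(seq_len(3L), axis)
  for (nm in names(masks)) {
    res2d <- proj[[nm]] & !overlap
    if (!any(res2d))
      stop(sprintf("organ '%s' is fully occluded in projection (empty residual)",
                   nm))
    # 3D voxels whose projected pixel survives
    m <- masks[[nm]]
    surv <- .expandAlongAxis(res2d, dim(m), axis)
    vRes <- sum(m & surv)
    vTot <- sum(m)
    out[[nm]] <- list(mask2d = res2d, factor = vTot / vRes,
                      voxelsTotal = vTot, voxelsResidual = vRes)
  }
  out
}

.expandAlongAxis <- function(mask2d, dims, axis) {
  # replicate a 2D mask along `axis` to the 3D grid
  arr <- array(FALSE, dims)
  if (axis == 2L) {
    for (j in seq_len(dims[2L])) arr[, j, ] <- mask2d
  } else if (axis == 1L) {
    for (i in seq_len(dims[1L])) arr[i, , ] <- mask2d
  } else {
    for (k in seq_len(dims[3L])) arr[, , k] <- mask2d
  }
  arr
}

#' Rescale a planar time-activity curve by a single SPECT measurement
#'
#' Multiplies every value of the planar curve by
#' \code{A_SPECT(t_ref) / A_planar(t_ref)}, anchoring the curve's absolute
#' scale to the SPECT VOI activity while preserving its shape (and hence the
#' fitted effective half-life exactly).
#'
#' @param tac a [TimeActivityCurve-class].
#' @param spectActivityMBq SPECT VOI activity at \code{tRefH}.
#' @param tRefH reference time; must be one of the curve's time points.
#' @return the rescaled [TimeActivityCurve-class] (method \code{"hybrid"}).
#' @export
hybridRescale <- function(tac, spectActivityMBq, tRefH) {
  i <- match(tRefH, tac@timesH)
  if (is.na(i))
    stop(sprintf("tRefH = %g h is not a time point of the curve (%s)",
                 tRefH, paste(tac@timesH, collapse = ", ")))
  ap <- tac@activitiesMBq[i]
  if (ap <= 0)
    stop("planar activity at the reference time must be > 0")
  timeActivityCurve(tac@organ, tac@timesH,
                    tac@activitiesMBq * (spectActivityMBq / ap),
                    method = "hybrid")
}

# ---------------------------------------------------------------------------
# Sphere recovery coefficients (partial-volume correction)
# ---------------------------------------------------------------------------

.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# radial profile of a unit-concentration ball of radius R blurred with an
# isotropic Gaussian of sd sigma (closed form)
.blurredBallProfile <- function(r, R, sigma) {
  small <- r < 1e-8 * R
  out <- numeric(length(r))
  if (any(small))
    out[small] <- .erf(R / (sqrt(2) * sigma)) -
      sqrt(2 / pi) * (R / sigma) * exp(-R^2 / (2 * sigma^2))
  rr <- r[!small]
  if (length(rr))
    out[!small] <-
      0.5 * (.erf((rr + R) / (sqrt(2) * sigma)) -
             .erf((rr - R) / (sqrt(2) * sigma))) -
      (sigma / (rr * sqrt(2 * pi))) *
        (exp(-(rr - R)^2 / (2 * sigma^2)) - exp(-(rr + R)^2 / (2 * sigma^2)))
  out
}

#' Sphere recovery coefficient for a Gaussian PSF
#'
#' Fraction of the activity of a uniform sphere that remains inside its own
#' boundary after convolution with an isotropic Gaussian PSF: the recovery
#' coefficient used to correct tumour activities for the partial volume
#' effect (corrected = measured / RC).
#'
#' @param model a [RecoveryModel-class] (carries the PSF FWHM in mm), or a
#'   numeric FWHM in mm.
#' @param volumeML sphere volume, mL (> 0).
#' @return RC in (0, 1]; monotonically increasing in volume, 1 for FWHM 0.
#' @examples
#' recoveryCoefficient(recoveryModel(10), volumeML = 4)
#' @export
recoveryCoefficient <- function(model, volumeML) {
  fwhm <- if (is(model, "RecoveryModel")) model@fwhmMm else model
  if (volumeML <= 0) stop("volume must be > 0")
  if (fwhm < 0) stop("FWHM must be >= 0")
  if (fwhm == 0) return(1)
  R <- (3 * volumeML * 1000 / (4 * pi))^(1 / 3)    # mm
  sigma <- fwhm * .FWHM_TO_SIGMA
  f <- function(r) .blurredBallProfile(r, R, sigma) * r^2
  int <- stats::integrate(f, 0, R, rel.tol = 1e-9)$value
  min((3 / R^3) * int, 1)
}

# ---------------------------------------------------------------------------
# Automatic background band placement
# ---------------------------------------------------------------------------

#' Place a background band next to an organ ROI
#'
#' Mirrors the clinical tool's automatic placement: a narrow vertical band
#' offset laterally from the organ ROI bounding box, spanning the organ's z
#' range, kept inside the body footprint and away from every organ ROI. The
#' preferred side is chosen automatically (the side with more valid pixels)
#' unless given.
#'
#' @param organMask logical matrix: the organ ROI.
#' @param forbidden logical matrix: union of all organ ROIs (pixels the band
#'   must avoid).
#' @param body logical matrix: body footprint the band must stay inside.
#' @param width band width, pixels.
#' @param gap gap between ROI bounding box and band, pixels.
#' @param side \code{"auto"}, \code{"left"} or \code{"right"} (x direction).
#' @return logical matrix: the band (non-empty), or an error if no valid
#'   placement exists.
#' @export
placeBackgroundRoi <- function(organMask, forbidden, body, width = 2L,
                               gap = 1L, side = "auto") {
  idx <- which(organMask, arr.ind = TRUE)
  xr <- range(idx[, 1L]); zr <- range(idx[, 2L])
  nx <- nrow(organMask)
  mk <- function(cols) {
    cols <- cols[cols >= 1L & cols <= nx]
    band <- matrix(FALSE, nx, ncol(organMask))
    if (length(cols)) band[cols, zr[1L]:zr[2L]] <- TRUE
    band & body & !forbidden
  }
  right <- mk(seq(xr[2L] + gap + 1L, length.out = width))
  left <- mk(seq(xr[1L] - gap - width, length.out = width))
  band <- switch(side,
    right = right, left = left,
    auto = if (sum(right) >= sum(left)) right else left)
  if (!any(band))
    stop("no valid background band placement next to the ROI")
  band
}
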