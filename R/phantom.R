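# Digital phantom generation: rasterised organs, analytic kinetics,
# quantitative activity volumes, attenuated conjugate-view projections.
#
# Geometry conventions (fixed across the package):
#   * axis order (x, y, z); the planar projection integrates along y;
#   * "anterior" means the detector sits on the -y side of the grid;
#   * voxel centres at (i - 0.5) * voxelSize mm, i = 1..n;
#   * masks are logical arrays on the common grid, disjoint in 3D.

.lambdaEff <- function(physicalHalfLife, bioHalfLife) {
  lp <- log(2) / physicalHalfLife
  lb <- if (is.finite(bioHalfLife)) log(2) / bioHalfLife else 0
  lp + lb
}

.axisCenters <- function(n, vox) (seq_len(n) - 0.5) * vox

.rasteriseShape <- function(shape, center, semiAxes, dims, voxelSize) {
  x <- .axisCenters(dims[1L], voxelSize[1L])
  y <- .axisCenters(dims[2L], voxelSize[2L])
  z <- .axisCenters(dims[3L], voxelSize[3L])
  if (shape %in% c("ellipsoid", "sphere")) {
    qx <- ((x - center[1L]) / semiAxes[1L])^2
    qy <- ((y - center[2L]) / semiAxes[2L])^2
    qz <- ((z - center[3L]) / semiAxes[3L])^2
    m <- outer(outer(qx, qy, `+`), qz, `+`) <= 1
  } else {                                    # box
    ix <- abs(x - center[1L]) <= semiAxes[1L]
    iy <- abs(y - center[2L]) <= semiAxes[2L]
    iz <- abs(z - center[3L]) <= semiAxes[3L]
    m <- outer(outer(ix, iy, `&`), iz, `&`)
  }
  dim(m) <- dims
  m
}

#' Rasterise a phantom specification into masks and tissue volumes
#'
#' Builds the voxel phantom every other stage consumes: one boolean 3D mask
#' per organ (mutually disjoint; a tumour is carved out of its host organ so
#' the 3D masks never overlap even though the tumour lies inside the host),
#' the body outline, and density (g/mL) and 208 keV attenuation (cm^-1)
#' volumes. Voxels with density below 0.5 g/mL get the lung attenuation
#' coefficient, other body voxels the soft-tissue coefficient, air gets zero.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [VoxelPhantom-class].
#' @section Errors: an organ whose analytic extent leaves the grid, or whose
#'   rasterised mask is empty, raises an error naming the organ; two organ
#'   definitions overlapping in 3D raise an error (overlap is allowed only in
#'   2D projection); a tumour extending beyond its host organ raises an
#'   error.
#' @examples
#' ps <- phantomSpec(c(24, 16, 24), 4, list(
#'   organSpec("ball", "sphere", c(48, 32, 48), 10, uptakeFraction = 0.05)))
#' ph <- buildPhantom(ps)
#' sum(ph@masks$ball)
#' @export
buildPhantom <- function(spec) {
  validObject(spec)
  dims <- spec@dim
  vox <- spec@voxelSize
  extent <- dims * vox

  body <- .rasteriseShape(spec@bodyShape, spec@bodyCenter, spec@bodySemiAxes,
                          dims, vox)

  organs <- spec@organs
  nm <- vapply(organs, slot, character(1), name = "name")
  tumour <- vapply(organs, slot, logical(1), name = "isTumour")
  host <- vapply(organs, slot, character(1), name = "hostOrgan")

  masks <- vector("list", length(organs))
  names(masks) <- nm
  for (i in seq_along(organs)) {
    o <- organs[[i]]
    if (any(o@center - o@semiAxes < 0) || any(o@center + o@semiAxes > extent))
      stop(sprintf("organ '%s' extends outside the grid", o@name))
    m <- .rasteriseShape(o@shape, o@center, o@semiAxes, dims, vox)
    if (!any(m))
      stop(sprintf("organ '%s' rasterises to an empty mask", o@name))
    masks[[i]] <- m
  }

  # tumours must sit inside their host; carve them out so 3D masks stay disjoint
  for (i in which(tumour & !is.na(host))) {
    hj <- match(host[i], nm)
    if (is.na(hj)) stop(sprintf("tumour '%s': host organ '%s' not found",
                                nm[i], host[i]))
    if (any(masks[[i]] & !masks[[hj]]))
      stop(sprintf("tumour '%s' extends outside host organ '%s'",
                   nm[i], host[i]))
    masks[[hj]] <- masks[[hj]] & !masks[[i]]
  }

  occupancy <- Reduce(`+`, lapply(masks, function(m) m * 1L),
                      accumulate = FALSE)
  if (length(masks) && max(occupancy) > 1L) {
    over <- which(occupancy > 1L)[1L]
    bad <- nm[vapply(masks, function(m) m[over], logical(1))]
    stop(sprintf("organs overlap in 3D (%s); only 2D projection overlap is allowed",
                 paste(bad, collapse = ", ")))
  }

  density <- array(0, dims)
  density[body] <- 1.03                       # generic soft tissue
  for (i in seq_along(masks)) density[masks[[i]]] <- organs[[i]]@density

  attenuation <- array(0, dims)
  attenuation[body] <- spec@muSoft
  lungish <- density < 0.5 & density > 0
  attenuation[lungish] <- spec@muLung

  new("VoxelPhantom", spec = spec, masks = masks, body = body,
      density = density, attenuation = attenuation)
}

#' Analytic organ activity at time t
#'
#' The generator's kinetic model is the same model class the analysis fits:
#' uptake fraction \code{f} of the administered activity at t = 0 washing out
#' as a single exponential with effective decay constant
#' \code{lambda_eff = ln2/T_phys + ln2/T_bio}.
#'
#' @param organ an [OrganSpec-class].
#' @param admin an [AdministrationRecord-class].
#' @param t time post injection, hours (>= 0).
#' @param physicalHalfLife physical half-life, hours.
#' @return activity in MBq (vectorised over \code{t}).
#' @examples
#' o <- organSpec("k", "sphere", c(50, 50, 50), 10, uptakeFraction = 0.1)
#' organActivity(o, administrationRecord(7), 0)   # 700 MBq
#' @export
organActivity <- function(organ, admin, t, physicalHalfLife = 159.528) {
  if (any(t < 0)) stop("t must be >= 0")
  lam <- .lambdaEff(physicalHalfLife, organ@bioHalfLife)
  admin@activityGBq * 1000 * organ@uptakeFraction * exp(-lam * t)
}

# --- Gaussian blur (separable, FFT, circular): kernel sums to one so the
#     global activity is conserved exactly; phantoms keep activity away from
#     the grid edge so wrap-around is negligible.
.kernel1d <- function(n, sigmaVox) {
  off <- ((seq_len(n) - 1 + floor(n / 2)) %% n) - floor(n / 2)
  if (sigmaVox <= 0) return(as.numeric(off == 0))
  k <- exp(-off^2 / (2 * sigmaVox^2))
  k / sum(k)
}

.gaussianBlur <- function(vol, fwhmMm, voxelSize) {
  if (fwhmMm == 0) return(vol)
  d <- dim(vol)
  sig <- fwhmMm * .FWHM_TO_SIGMA / voxelSize[seq_along(d)]
  ks <- lapply(seq_along(d), function(i) .kernel1d(d[i], sig[i]))
  K <- ks[[1L]]
  for (i in seq_along(d)[-1L]) K <- outer(K, ks[[i]])
  dim(K) <- d
  out <- Re(fft(fft(vol) * fft(K), inverse = TRUE)) / prod(d)
  out
}

#' Render a quantitative activity volume
#'
#' Distributes each organ's activity uniformly over its mask (MBq/voxel), the
#' background activity uniformly over the body remainder, and optionally
#' applies an isotropic Gaussian PSF. This emulates a reconstructed,
#' attenuation-corrected, calibrated SPECT volume; tomographic reconstruction
#' itself is not modelled.
#'
#' @param phantom a [VoxelPhantom-class].
#' @param organActivities named numeric vector, MBq per organ (names must
#'   match mask names; missing organs get 0).
#' @param backgroundActivity background (body remainder) activity, MBq.
#' @param psfFwhmMm Gaussian PSF FWHM in mm (0 = no blur).
#' @return numeric 3D array, MBq per voxel. Without blur the sum over each
#'   organ mask equals that organ's activity exactly; with blur the global
#'   sum is conserved.
#' @export
renderActivityVolume <- function(phantom, organActivities,
                                 backgroundActivity = 0, psfFwhmMm = 0) {
  if (psfFwhmMm < 0) stop("PSF FWHM must be >= 0")
  vol <- array(0, dim(phantom@body))
  for (nm in names(phantom@masks)) {
    a <- if (nm %in% names(organActivities)) organActivities[[nm]] else 0
    if (a == 0) next
    m <- phantom@masks[[nm]]
    vol[m] <- vol[m] + a / sum(m)
  }
  if (backgroundActivity > 0) {
    bg <- phantom@body
    for (m in phantom@masks) bg <- bg & !m
    vol[bg] <- vol[bg] + backgroundActivity / sum(bg)
  }
  .gaussianBlur(vol, psfFwhmMm, phantom@spec@voxelSize)
}

#' Project an activity volume to an attenuated planar count image
#'
#' Discretises \code{counts(x, z) = duration * sensitivity *
#' sum_y a(x, y, z) * exp(-integral mu dl)} along the y (anterior-posterior)
#' axis, with the attenuation path integral taken from each voxel centre to
#' the detector (mid-voxel convention, so opposed projections of a voxel see
#' complementary path lengths summing to the full body thickness). The
#' posterior image is returned as a rear detector acquires it: mirrored along
#' x relative to the anterior frame.
#'
#' @param activityVol 3D activity array, MBq/voxel.
#' @param attenuationVol 3D attenuation array, cm^-1, same grid.
#' @param voxelSize voxel size, mm (length 3).
#' @param direction \code{"anterior"} (detector at -y) or
#'   \code{"posterior"}.
#' @param sensitivity system sensitivity, counts s^-1 MBq^-1.
#' @param duration acquisition duration, s.
#' @param noise Poisson-sample the counts?
#' @param seed integer seed used (locally, without disturbing the global RNG
#'   stream) when \code{noise = TRUE}; NULL draws from the current stream.
#' @return count matrix indexed (x, z).
#' @export
projectPlanar <- function(activityVol, attenuationVol, voxelSize,
                          direction = c("anterior", "posterior"),
                          sensitivity = 10, duration = 300, noise = FALSE,
                          seed = NULL) {
  direction <- match.arg(direction)
  if (!identical(dim(activityVol), dim(attenuationVol)))
    stop("activity and attenuation volumes must share the same grid")
  d <- dim(activityVol)
  nx <- d[1L]; ny <- d[2L]; nz <- d[3L]
  dyCm <- voxelSize[2L] / 10

  img <- matrix(0, nx, nz)
  cum <- matrix(0, nx, nz)
  jseq <- if (direction == "anterior") seq_len(ny) else rev(seq_len(ny))
  for (j in jseq) {
    mu <- attenuationVol[, j, ]
    # path from voxel centre to the detector-side face of the slab
    att <- exp(-(cum + 0.5 * mu) * dyCm)
    img <- img + activityVol[, j, ] * att
    cum <- cum + mu
  }
  img <- img * sensitivity * duration
  if (direction == "posterior") img <- img[rev(seq_len(nx)), , drop = FALSE]
  if (noise) {
    img <- .withLocalSeed(seed, {
      matrix(as.numeric(stats::rpois(length(img), img)), nx, nz)
    })
  }
  img
}

.withLocalSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Blur a 2D count image with a Gaussian planar PSF
#'
#' @param img count matrix.
#' @param fwhmMm PSF FWHM, mm.
#' @param pixelSize pixel size, mm (length 2: x, z).
#' @return blurred matrix (sum conserved).
#' @export
blurPlanar <- function(img, fwhmMm, pixelSize) {
  if (fwhmMm < 0) stop("PSF FWHM must be >= 0")
  .gaussianBlur(img, fwhmMm, pixelSize)
}

#' Simulate a complete patient-equivalent imaging study
#'
#' Runs the full acquisition protocol on a phantom: at every planar time
#' point an anterior/posterior conjugate-view pair (attenuated projection,
#' planar PSF, calibration syringe rendered below the feet, optional Poisson
#' noise), and at the configured SPECT time points a quantitative activity
#' volume with the SPECT PSF applied (optional relative Gaussian noise). The
#' ground-truth kinetics record (per-organ uptake fraction, effective decay
#' constant, analytic residence time f/lambda_eff, mass and local-deposition
#' dose) is attached for parameter-recovery checks.
#'
#' The whole simulation is driven by \code{acq@seed}: identical
#' specification plus seed gives a bit-identical study.
#'
#' @param phantom a [PhantomSpec-class] or prebuilt [VoxelPhantom-class].
#' @param acq an [AcquisitionSpec-class].
#' @param admin an [AdministrationRecord-class].
#' @param calibration a [CalibrationStandard-class]; its \code{location}
#'   pixel block must lie outside the body footprint.
#' @param electronEnergyMeV mean electron energy per decay used for the truth
#'   doses, MeV.
#' @return a [StudyDataset-class].
#' @export
simulateStudy <- function(phantom, acq = acquisitionSpec(),
                          admin = administrationRecord(7.2),
                          calibration = calibrationStandard(),
                          electronEnergyMeV = .LU_DELTA_E) {
  ph <- if (is(phantom, "PhantomSpec")) buildPhantom(phantom) else phantom
  validObject(acq)
  if (!all(acq@spectTimes %in% acq@timePoints))
    stop("SPECT time points must be a subset of the planar time points")
  spec <- ph@spec
  vox <- spec@voxelSize
  organs <- spec@organs
  nm <- organNames(ph)
  adminMBq <- admin@activityGBq * 1000

  loc <- calibration@location
  d <- dim(ph@body)
  if (loc[2L] > d[1L] || loc[4L] > d[3L])
    stop("calibration standard location outside the planar field of view")
  bodyFoot <- apply(ph@body, c(1L, 3L), any)
  if (any(bodyFoot[loc[1L]:loc[2L], loc[3L]:loc[4L]]))
    stop("calibration standard location overlaps the body footprint")

  lamPhys <- log(2) / acq@physicalHalfLife
  lams <- vapply(organs, function(o)
    .lambdaEff(acq@physicalHalfLife, o@bioHalfLife), numeric(1))
  names(lams) <- nm
  fs <- vapply(organs, slot, numeric(1), name = "uptakeFraction")
  names(fs) <- nm
  lamBg <- .lambdaEff(acq@physicalHalfLife, spec@backgroundHalfLife)

  anterior <- posterior <- vector("list", length(acq@timePoints))
  spectVols <- list()

  .withLocalSeed(acq@seed, {
    for (i in seq_along(acq@timePoints)) {
      t <- acq@timePoints[i]
      acts <- adminMBq * fs * exp(-lams * t)
      bgAct <- adminMBq * spec@backgroundUptake * exp(-lamBg * t)
      vol <- renderActivityVolume(ph, acts, bgAct, psfFwhmMm = 0)

      a <- projectPlanar(vol, ph@attenuation, vox, "anterior",
                         acq@planarSensitivity, acq@planarDuration)
      p <- projectPlanar(vol, ph@attenuation, vox, "posterior",
                         acq@planarSensitivity, acq@planarDuration)

      # calibration syringe: unattenuated, below the feet, same in both views;
      # posterior mirroring maps the block to mirrored x indices
      calAct <- calibration@activityMBq * exp(-lamPhys * (t - calibration@refTimeH))
      calCounts <- acq@planarDuration * acq@planarSensitivity * calAct
      xs <- loc[1L]:loc[2L]; zs <- loc[3L]:loc[4L]
      per <- calCounts / (length(xs) * length(zs))
      a[xs, zs] <- a[xs, zs] + per
      p[d[1L] + 1L - xs, zs] <- p[d[1L] + 1L - xs, zs] + per

      if (acq@planarFwhm > 0) {
        a <- blurPlanar(a, acq@planarFwhm, vox[c(1L, 3L)])
        p <- blurPlanar(p, acq@planarFwhm, vox[c(1L, 3L)])
      }
      if (acq@noise) {
        a <- matrix(as.numeric(stats::rpois(length(a), pmax(a, 0))),
                    d[1L], d[3L])
        p <- matrix(as.numeric(stats::rpois(length(p), pmax(p, 0))),
                    d[1L], d[3L])
      }
      anterior[[i]] <- a
      posterior[[i]] <- p

      if (t %in% acq@spectTimes) {
        sv <- renderActivityVolume(ph, acts, bgAct, psfFwhmMm = acq@spectFwhm)
        if (acq@spectNoiseSd > 0)
          sv <- pmax(sv * (1 + acq@spectNoiseSd *
                             stats::rnorm(length(sv))), 0)
        dim(sv) <- d
        spectVols[[as.character(t)]] <- sv
      }
    }
  })

  voxMl <- prod(vox) / 1000
  truth <- data.frame(
    organ = nm,
    f = unname(fs),
    lambda_eff_per_h = unname(lams),
    tau_h = unname(ifelse(fs > 0, fs / lams, 0)),
    mass_g = vapply(seq_along(nm), function(i)
      sum(ph@masks[[i]]) * voxMl * organs[[i]]@density, numeric(1)),
    is_tumour = vapply(organs, slot, logical(1), name = "isTumour"),
    stringsAsFactors = FALSE)
  truth$dose_Gy <- ifelse(truth$tau_h > 0,
    vapply(seq_len(nrow(truth)), function(i)
      selfDose(truth$tau_h[i], admin@activityGBq, truth$mass_g[i],
               electronEnergyMeV), numeric(1)), 0)
  truth$dpa_Gy_per_GBq <- truth$dose_Gy / admin@activityGBq

  new("StudyDataset", timesH = acq@timePoints, anterior = anterior,
      posterior = posterior, spectTimesH = acq@spectTimes,
      spect = spectVols, phantom = ph, admin = admin,
      calibration = calibration, acquisition = acq, truth = truth)
}

# ---------------------------------------------------------------------------
# ROI perturbation (simulated observers)
# ---------------------------------------------------------------------------

.shiftArray <- function(arr, by) {
  d <- dim(arr)
  out <- array(FALSE, d)
  src <- dst <- vector("list", length(d))
  for (k in seq_along(d)) {
    b <- by[k]
    if (abs(b) >= d[k]) return(out)
    if (b >= 0) { src[[k]] <- seq_len(d[k] - b); dst[[k]] <- src[[k]] + b }
    else        { src[[k]] <- seq(1 - b, d[k]);  dst[[k]] <- src[[k]] + b }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

.morph <- function(mask, magnitude, dilate = TRUE) {
  d <- dim(mask)
  nd <- length(d)
  if (nd == 2L) { dim(mask) <- c(d, 1L); d <- dim(mask) }
  out <- mask
  offs <- expand.grid(rep(list(-1:1), 3L))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (nd == 2L) offs <- offs[offs[[3L]] == 0, , drop = FALSE]
  for (it in seq_len(magnitude)) {
    acc <- out
    for (r in seq_len(nrow(offs))) {
      sh <- .shiftArray(out, as.integer(offs[r, ]))
      # zero-filled shifts make erosion shave the array border automatically
      acc <- if (dilate) acc | sh else acc & sh
    }
    out <- acc
  }
  if (nd == 2L) dim(out) <- d[1:2]
  out
}

#' Perturb an ROI/VOI mask (simulated observer variability)

#' Emulates independent observers redrawing an organ region: morphological
#' dilation or erosion by whole voxels, or a rigid shift. The input mask is
#' never modified; results are reproducible under a fixed seed.
#'
#' @param mask logical matrix (2D ROI) or 3D array (VOI).
#' @param mode \code{"dilate"}, \code{"erode"} or \code{"shift"}.
#' @param magnitude number of voxels (dilate/erode) or maximal per-axis shift
#'   (random shift).
#' @param shift explicit integer shift vector (length = rank of mask); if
#'   NULL and \code{mode = "shift"}, a random shift with per-axis components
#'   in \code{-magnitude..magnitude} is drawn (seeded).
#' @param seed integer seed for the random shift (NULL = current RNG stream).
#' @return the perturbed logical mask.
#' @section Errors: erosion that empties the mask raises an error.
#' @export
perturbRoi <- function(mask, mode = c("dilate", "erode", "shift"),
                       magnitude = 1, shift = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (magnitude < 0) stop("magnitude must be >= 0")
  if (magnitude == 0 && is.null(shift)) return(mask)
  out <- switch(mode,
    dilate = .morph(mask, magnitude, dilate = TRUE),
    erode  = .morph(mask, magnitude, dilate = FALSE),
    shift  = {
      nd <- length(dim(mask))
      if (is.null(shift))
        shift <- .withLocalSeed(seed,
          sample(seq(-magnitude, magnitude), nd, replace = TRUE))
      if (length(shift) != nd) stop("shift must have one entry per mask axis")
      d <- dim(mask)
      m <- mask
      if (nd == 2L) { dim(m) <- c(d, 1L); shift <- c(shift, 0L) }
      r <- .shiftArray(m, as.integer(shift))
      if (nd == 2L) dim(r) <- d
      r
    })
  if (mode == "erode" && !any(out))
    stop("erosion emptied the mask")
  out
}
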