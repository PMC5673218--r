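# The three dosimetry scenarios (multi-SPECT-CT, planar-only, hybrid) run
# end-to-end on a StudyDataset, plus cohort-level scenario comparison and
# inter-observer concordance.

.gmImage <- function(study, i)
  geometricMean(study@anterior[[i]], study@posterior[[i]])

# syringe counts are extracted over the location block grown by a margin so
# the planar PSF tail is recaptured (a generous ROI around the standard,
# drawn clear of the patient: body-footprint pixels are excluded)
.calibrationCounts <- function(study, gm, margin = 3L) {
  loc <- study@calibration@location
  d <- dim(gm)
  xs <- max(1L, loc[1L] - margin):min(d[1L], loc[2L] + margin)
  zs <- max(1L, loc[3L] - margin):min(d[2L], loc[4L] + margin)
  roi <- matrix(FALSE, d[1L], d[2L])
  roi[xs, zs] <- TRUE
  roi <- roi & !apply(study@phantom@body, c(1L, 3L), any)
  sum(gm[roi])
}

.planarSensitivity <- function(study, gm, timeH) {
  sensitivityFromStandard(.calibrationCounts(study, gm),
                          study@acquisition@planarDuration,
                          study@calibration, scanTimeH = timeH,
                          physicalHalfLife = study@acquisition@physicalHalfLife)
}

.thicknessSpecFromVoxels <- function(phantom, mask3d, foot2d) {
  dyCm <- phantom@spec@voxelSize[2L] / 10
  dOrgan <- sum(mask3d) * dyCm / sum(foot2d)
  bodyDepth <- apply(phantom@body, c(1L, 3L), sum) * dyCm
  dBody <- mean(bodyDepth[foot2d])
  backgroundCorrectionSpec(min(dOrgan, dBody), dBody)
}

.syringeBlock <- function(study, margin = 3L) {
  d <- dim(study@phantom@body)[c(1L, 3L)]
  loc <- study@calibration@location
  blk <- matrix(FALSE, d[1L], d[2L])
  xs <- max(1L, loc[1L] - margin):min(d[1L], loc[2L] + margin)
  zs <- max(1L, loc[3L] - margin):min(d[2L], loc[4L] + margin)
  blk[xs, zs] <- TRUE
  blk
}

.isTumourMap <- function(study) {
  organs <- study@phantom@spec@organs
  setNames(vapply(organs, slot, logical(1), name = "isTumour"),
           vapply(organs, slot, character(1), name = "name"))
}

.organDensityMap <- function(study) {
  organs <- study@phantom@spec@organs
  setNames(vapply(organs, slot, numeric(1), name = "density"),
           vapply(organs, slot, character(1), name = "name"))
}

# ROI2D set for the planar path; maskSet overrides the 2D masks (hybrid
# residuals). A tumour whose band cannot avoid every organ ROI falls back to
# a band over its host organ, mirroring the clinical situation of a lesion
# surrounded by liver.
.planarRoiSet <- function(study, maskSet = NULL) {
  ph <- study@phantom
  bodyFoot <- apply(ph@body, c(1L, 3L), any)
  proj <- lapply(ph@masks, projectVoi)
  masks2d <- if (is.null(maskSet)) proj else maskSet
  forbiddenAll <- Reduce(`|`, proj) | .syringeBlock(study)
  tumourMap <- .isTumourMap(study)
  hostMap <- setNames(
    vapply(ph@spec@organs, slot, character(1), name = "hostOrgan"),
    names(tumourMap))
  rois <- list()
  for (nm in names(masks2d)) {
    band <- tryCatch(
      placeBackgroundRoi(masks2d[[nm]], forbiddenAll, bodyFoot),
      error = function(e) {
        if (isTRUE(tumourMap[[nm]]) && !is.na(hostMap[[nm]])) {
          relaxed <- forbiddenAll & !proj[[hostMap[[nm]]]]
          placeBackgroundRoi(masks2d[[nm]], relaxed, bodyFoot)
        } else stop(e)
      })
    rois[[nm]] <- new("ROI2D", organ = nm, mask = masks2d[[nm]],
                      background = band)
  }
  rois
}

.doseRow <- function(study, organ, tauH, massG, isTumour, rcFwhm,
                     scenario, electronEnergyMeV, flags = "") {
  admin <- study@admin@activityGBq
  if (isTumour) {
    volMl <- massG / 1.06
    rc <- recoveryCoefficient(rcFwhm, volMl)
    dose <- sphereDose(tauH, admin, massG, electronEnergyMeV, rc = rc)
  } else {
    tab <- defaultDoseFactorTable(organ, electronEnergyMeV)
    dose <- organDose(setNames(tauH, organ), admin, setNames(massG, organ),
                      tab, organ)
  }
  data.frame(organ = organ, scenario = scenario, tau_h = tauH,
             mass_g = massG, dose_Gy = dose,
             dpa_Gy_per_GBq = dosePerActivity(dose, admin),
             is_tumour = isTumour, flags = flags, stringsAsFactors = FALSE)
}

.assembleScenario <- function(study, scenario, tacs, rcFwhm,
                              electronEnergyMeV, flags = NULL) {
  ph <- study@phantom
  voxMl <- prod(ph@spec@voxelSize) / 1000
  tumourMap <- .isTumourMap(study)
  densMap <- .organDensityMap(study)
  fits <- lapply(tacs, fitMonoexp)
  rows <- list()
  for (nm in names(tacs)) {
    tau <- residenceTime(fits[[nm]], study@admin)
    dens <- if (tumourMap[[nm]]) 1.06 else densMap[[nm]]
    mass <- organMass(ph@masks[[nm]], voxMl, dens)$mass_g
    rows[[nm]] <- .doseRow(study, nm, tau, mass, tumourMap[[nm]], rcFwhm,
                           scenario, electronEnergyMeV,
                           flags = if (is.null(flags)) "" else flags[[nm]])
  }
  new("ScenarioResult", scenario = scenario, tacs = tacs, fits = fits,
      doses = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Multi-SPECT-CT scenario
#'
#' Quantifies every organ from its 3D VOI on the SPECT volume of every time
#' point (VOIs are the study's 3D masks, overlap-free by construction), fits
#' the mono-exponential, and converts residence times to doses with
#' individual organ masses. Requires a SPECT volume at every planar time
#' point.
#'
#' @param study a [StudyDataset-class].
#' @param calibrationFactor SPECT calibration factor (1 for simulated
#'   quantitative volumes).
#' @param electronEnergyMeV mean electron energy per decay, MeV.
#' @return a [ScenarioResult-class].
#' @export
runMultiSpect <- function(study, calibrationFactor = 1,
                          electronEnergyMeV = .LU_DELTA_E) {
  missing <- setdiff(study@timesH, study@spectTimesH)
  if (length(missing))
    stop(sprintf(
      "no SPECT volume at %s h; the multi-SPECT-CT scenario needs SPECT at every time point (consider the hybrid scenario)",
      paste(missing, collapse = ", ")))
  ph <- study@phantom
  tacs <- list()
  for (nm in organNames(study)) {
    acts <- vapply(as.character(study@timesH), function(tt)
      voiActivity(study@spect[[tt]], ph@masks[[nm]], calibrationFactor),
      numeric(1))
    tacs[[nm]] <- timeActivityCurve(nm, study@timesH, acts, method = "spect")
  }
  .assembleScenario(study, "multi_spect", tacs,
                    rcFwhm = study@acquisition@spectFwhm, electronEnergyMeV)
}

#' Planar-only scenario
#'
#' Geometric-mean images per time point; organ ROIs are the projected 3D
#' masks (projection overlaps allowed, as in the clinical planar workflow);
#' the background band is re-placed next to each ROI at each time point and
#' subtracted with the thickness weighting factor; counts are calibrated
#' through the co-scanned syringe. No attenuation correction is applied --
#' with attenuation on, planar estimates are systematically biased, organ
#' overlap biasing them upward and photon attenuation downward.
#'
#' @inheritParams runMultiSpect
#' @return a [ScenarioResult-class].
#' @export
runPlanar <- function(study, electronEnergyMeV = .LU_DELTA_E) {
  ph <- study@phantom
  rois <- .planarRoiSet(study)
  wfs <- lapply(organNames(study), function(nm) thicknessFromMasks(ph, nm))
  names(wfs) <- organNames(study)
  nt <- length(study@timesH)
  acts <- matrix(0, nt, length(rois),
                 dimnames = list(NULL, names(rois)))
  floored <- setNames(rep("", length(rois)), names(rois))
  for (i in seq_len(nt)) {
    gm <- .gmImage(study, i)
    sens <- .planarSensitivity(study, gm, study@timesH[i])
    for (nm in names(rois)) {
      r <- planarOrganActivity(gm, rois[[nm]], wfs[[nm]]@wf, sens,
                               study@acquisition@planarDuration)
      acts[i, nm] <- r$activityMBq
      if (r$floored)
        floored[nm] <- paste0(floored[nm],
                              sprintf("floored@%gh;", study@timesH[i]))
    }
  }
  tacs <- lapply(names(rois), function(nm)
    timeActivityCurve(nm, study@timesH, acts[, nm], method = "planar"))
  names(tacs) <- names(rois)
  .assembleScenario(study, "planar", tacs,
                    rcFwhm = study@acquisition@planarFwhm, electronEnergyMeV,
                    flags = as.list(floored))
}

#' Hybrid scenario: planar time-activity curves rescaled by a single SPECT
#'
#' 3D VOIs (taken at the SPECT nominally acquired at \code{tRefH}) are
#' projected onto the geometric-mean images; 2D pixels claimed by more than
#' one (non-tumour) organ are removed and the measured counts substituted by
#' the organ's residual-volume mean concentration (factor
#' \code{V_total/V_residual}); the resulting planar curve is rescaled by the
#' SPECT VOI activity at the reference time. Tumour lesions lying inside a
#' host organ are exempt from overlap removal (their projection is wholly
#' contained in the host's) and quantified from their own projected ROI.
#'
#' @inheritParams runMultiSpect
#' @param tRefH nominal SPECT reference time, h (default 24); matched to the
#'   nearest planar time point within +/- 2 h.
#' @return a [ScenarioResult-class].
#' @export
runHybrid <- function(study, tRefH = 24, calibrationFactor = 1,
                      electronEnergyMeV = .LU_DELTA_E) {
  dt <- abs(study@timesH - tRefH)
  i0 <- which.min(dt)
  if (dt[i0] > 2)
    stop(sprintf("no planar time point within 2 h of t_ref = %g h (available: %s)",
                 tRefH, paste(study@timesH, collapse = ", ")))
  tRef <- study@timesH[i0]
  if (!tRef %in% study@spectTimesH)
    stop(sprintf("no SPECT volume at %g h (SPECT available at: %s)",
                 tRef, paste(study@spectTimesH, collapse = ", ")))
  spectRef <- study@spect[[as.character(tRef)]]

  ph <- study@phantom
  tumourMap <- .isTumourMap(study)
  organNm <- organNames(study)
  solid <- organNm[!tumourMap[organNm]]

  sub <- removeOverlapAndSubstitute(ph@masks[solid])
  masks2d <- lapply(sub, `[[`, "mask2d")
  factors <- vapply(sub, `[[`, numeric(1), "factor")
  for (nm in organNm[tumourMap[organNm]]) {        # tumours: ROI as projected
    masks2d[[nm]] <- projectVoi(ph@masks[[nm]])
    factors[nm] <- 1
  }
  rois <- .planarRoiSet(study, maskSet = masks2d[organNm])

  # thickness from the surviving part of each organ
  wfs <- list()
  for (nm in organNm) {
    surv <- .expandAlongAxis(masks2d[[nm]], dim(ph@body), 2L)
    wfs[[nm]] <- .thicknessSpecFromVoxels(ph, ph@masks[[nm]] & surv,
                                          masks2d[[nm]])
  }

  nt <- length(study@timesH)
  acts <- matrix(0, nt, length(organNm), dimnames = list(NULL, organNm))
  floored <- setNames(rep("", length(organNm)), organNm)
  for (i in seq_len(nt)) {
    gm <- .gmImage(study, i)
    sens <- .planarSensitivity(study, gm, study@timesH[i])
    for (nm in organNm) {
      r <- planarOrganActivity(gm, rois[[nm]], wfs[[nm]]@wf, sens,
                               study@acquisition@planarDuration)
      acts[i, nm] <- r$activityMBq * factors[[nm]]
      if (r$floored)
        floored[nm] <- paste0(floored[nm],
                              sprintf("floored@%gh;", study@timesH[i]))
    }
  }

  tacs <- list()
  for (nm in organNm) {
    planarTac <- timeActivityCurve(nm, study@timesH, acts[, nm],
                                   method = "planar")
    aSpect <- voiActivity(spectRef, ph@masks[[nm]], calibrationFactor)
    tacs[[nm]] <- hybridRescale(planarTac, aSpect, tRef)
  }
  .assembleScenario(study, "hybrid", tacs,
                    rcFwhm = study@acquisition@spectFwhm, electronEnergyMeV,
                    flags = as.list(floored))
}

#' Run one scenario by name
#'
#' @param study a [StudyDataset-class].
#' @param scenario \code{"multi_spect"}, \code{"planar"} or \code{"hybrid"}.
#' @param ... passed to the scenario runner.
#' @return a [ScenarioResult-class].
#' @export
runScenario <- function(study,
                        scenario = c("multi_spect", "planar", "hybrid"),
                        ...) {
  scenario <- match.arg(scenario)
  switch(scenario,
         multi_spect = runMultiSpect(study, ...),
         planar = runPlanar(study, ...),
         hybrid = runHybrid(study, ...))
}

#' Run all three scenarios on a study
#'
#' @param study a [StudyDataset-class].
#' @param tRefH hybrid SPECT reference time, h.
#' @return named list of three [ScenarioResult-class] objects.
#' @export
runAllScenarios <- function(study, tRefH = 24) {
  list(multi_spect = runMultiSpect(study),
       planar = runPlanar(study),
       hybrid = runHybrid(study, tRefH = tRefH))
}

# ---------------------------------------------------------------------------
# Cohort comparison
# ---------------------------------------------------------------------------

#' Long per-study dose table from scenario results
#'
#' @param results named list (one element per study) of named lists of
#'   [ScenarioResult-class] objects.
#' @return data.frame: study, organ, scenario, dpa_Gy_per_GBq.
#' @export
cohortDoseTable <- function(results) {
  if (is.null(names(results)))
    names(results) <- paste0("study", seq_along(results))
  rows <- list()
  for (st in names(results)) {
    for (res in results[[st]]) {
      d <- res@doses
      rows[[length(rows) + 1L]] <- data.frame(
        study = st, organ = d$organ, scenario = res@scenario,
        dpa_Gy_per_GBq = d$dpa_Gy_per_GBq, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Median DpA ratios relative to the multi-SPECT-CT scenario
#'
#' Per-organ ratio of per-scenario median dose-per-activity values, both at
#' full precision and rounded to one decimal for report parity with clinical
#' summaries ("increased by a factor of ...").
#'
#' @param multi,hybrid,planar named numeric vectors of per-organ median DpA
#'   (same organ names).
#' @return data.frame: organ, the three medians, hybrid_multi, planar_multi,
#'   and their one-decimal rounded versions.
#' @examples
#' medianRatios(c(kidneys = 0.413), c(kidneys = 0.503), c(kidneys = 0.647))
#' @export
medianRatios <- function(multi, hybrid, planar) {
  organs <- names(multi)
  if (!setequal(organs, names(hybrid)) || !setequal(organs, names(planar)))
    stop("the three median vectors must cover the same organs")
  hm <- hybrid[organs] / multi[organs]
  pm <- planar[organs] / multi[organs]
  data.frame(organ = organs,
             median_multi = unname(multi[organs]),
             median_hybrid = unname(hybrid[organs]),
             median_planar = unname(planar[organs]),
             hybrid_multi = unname(hm), planar_multi = unname(pm),
             hybrid_multi_1dp = round(unname(hm), 1),
             planar_multi_1dp = round(unname(pm), 1),
             stringsAsFactors = FALSE)
}

.friedmanStat <- function(mat) {
  # mat: studies x scenarios; returns statistic handling the all-tied case
  if (all(apply(mat, 1L, function(r) diff(range(r)) == 0)))
    return(list(statistic = 0, df = ncol(mat) - 1L, p = 1))
  ft <- stats::friedman.test(mat)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p = ft$p.value)
}

.wilcoxPaired <- function(x, y) {
  d <- x - y
  if (all(d == 0)) return(list(statistic = 0, p = 1))
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                            exact = length(d) <= 25,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Compare scenario doses across a cohort
#'
#' Per organ: Friedman test across the three scenarios (>= 3 studies
#' required), pairwise Wilcoxon signed-rank tests of hybrid and planar
#' against the multi-SPECT-CT scenario (exact distribution for n <= 25,
#' normal approximation with continuity correction otherwise; two-sided),
#' and the median-DpA ratio table.
#'
#' @param doses long data.frame (study, organ, scenario, dpa_Gy_per_GBq), as
#'   produced by [cohortDoseTable()].
#' @return a [ScenarioComparison-class].
#' @export
compareScenarios <- function(doses) {
  need <- c("study", "organ", "scenario", "dpa_Gy_per_GBq")
  if (!all(need %in% names(doses)))
    stop(paste("doses needs columns:", paste(need, collapse = ", ")))
  scns <- c("multi_spect", "hybrid", "planar")
  if (!setequal(unique(doses$scenario), scns))
    stop("doses must contain exactly the scenarios multi_spect, hybrid, planar")
  studies <- unique(doses$study)
  if (length(studies) < 3L) stop("need >= 3 studies for the Friedman test")
  organSets <- lapply(split(doses$organ, doses$study), unique)
  if (!all(vapply(organSets, setequal, logical(1), y = organSets[[1L]])))
    stop("unequal organ sets across studies")
  organs <- sort(organSets[[1L]])

  fr <- wl <- rt <- list()
  for (og in organs) {
    sub <- doses[doses$organ == og, ]
    mat <- sapply(scns, function(s) {
      ss <- sub[sub$scenario == s, ]
      ss$dpa_Gy_per_GBq[match(studies, ss$study)]
    })
    f <- .friedmanStat(mat)
    fr[[og]] <- data.frame(organ = og, statistic = f$statistic, df = f$df,
                           p_value = f$p, stringsAsFactors = FALSE)
    for (s in c("hybrid", "planar")) {
      w <- .wilcoxPaired(mat[, s], mat[, "multi_spect"])
      wl[[paste(og, s)]] <- data.frame(
        organ = og, comparison = paste0(s, "_vs_multi_spect"),
        statistic = w$statistic, p_value = w$p, stringsAsFactors = FALSE)
    }
    med <- apply(mat, 2L, stats::median)
    rt[[og]] <- medianRatios(setNames(med["multi_spect"], og),
                             setNames(med["hybrid"], og),
                             setNames(med["planar"], og))
  }
  new("ScenarioComparison", doses = doses,
      friedman = do.call(rbind, c(fr, list(make.row.names = FALSE))),
      wilcoxon = do.call(rbind, c(wl, list(make.row.names = FALSE))),
      ratios = do.call(rbind, c(rt, list(make.row.names = FALSE))))
}

# ---------------------------------------------------------------------------
# Kendall's W and observer simulation
# ---------------------------------------------------------------------------

#' Kendall's coefficient of concordance
#'
#' Tie-corrected W over an observers x items matrix of extracted values,
#' with the chi-square approximation p-value and, optionally, a seeded
#' permutation p-value (independent permutation of each observer's ratings).
#' Constant rows are fully tied, not an error.
#'
#' @param mat numeric matrix, rows = observers (>= 2), columns = items
#'   (>= 2).
#' @param permutations number of permutations for the permutation p-value
#'   (0 = skip).
#' @param seed integer seed for the permutation test.
#' @return an [ObserverAgreementResult-class].
#' @examples
#' kendallsW(rbind(c(1, 2, 3, 4), c(1, 2, 3, 4)))   # W = 1
#' @export
kendallsW <- function(mat, permutations = 0L, seed = NULL) {
  mat <- as.matrix(mat)
  m <- nrow(mat); n <- ncol(mat)
  if (m < 2L) stop("need >= 2 observers")
  if (n < 2L) stop("need >= 2 items")
  Wstat <- function(x) {
    rk <- t(apply(x, 1L, rank))
    R <- colSums(rk)
    S <- sum((R - mean(R))^2)
    Tsum <- sum(apply(rk, 1L, function(r) {
      tt <- table(r)
      sum(tt^3 - tt)
    }))
    den <- m^2 * (n^3 - n) - m * Tsum
    if (den <= 0) 0 else 12 * S / den
  }
  W <- Wstat(mat)
  chisq <- m * (n - 1) * W
  pChisq <- stats::pchisq(chisq, df = n - 1L, lower.tail = FALSE)
  pPerm <- NA_real_
  if (permutations > 0L) {
    pPerm <- .withLocalSeed(seed, {
      hits <- 0L
      for (b in seq_len(permutations)) {
        perm <- t(apply(mat, 1L, sample))
        if (Wstat(perm) >= W - 1e-12) hits <- hits + 1L
      }
      (hits + 1) / (permutations + 1)
    })
  }
  new("ObserverAgreementResult", W = max(0, min(W, 1)), pChisq = pChisq,
      pPermutation = pPerm, nObservers = m, nItems = as.integer(n))
}

#' Simulated inter-observer ROI/VOI study
#'
#' Emulates independent observers re-delineating one organ on every study of
#' a cohort: each observer applies a seeded random perturbation (rigid shift
#' plus optional one-voxel dilation/erosion) to the 3D VOI and, separately,
#' to the projected 2D ROI, and the counts extracted under the perturbed
#' regions (SPECT voxel sums for 3D; geometric-mean counts for 2D) are rated
#' for concordance with Kendall's W. With projection overlap present, 2D
#' delineations pick up counts from superimposed organs, so 2D concordance is
#' expected to sit below 3D concordance.
#'
#' @param studies a list of [StudyDataset-class] (the items rated), or a
#'   single study (its time points are then the items).
#' @param organ organ to delineate.
#' @param nObservers number of observers (>= 2).
#' @param magnitude perturbation magnitude in voxels (0 = identical
#'   observers).
#' @param seed integer seed; the whole simulation is reproducible under it.
#' @param tRefH preferred SPECT time point for count extraction.
#' @param permutations permutations for the W p-values.
#' @return list with elements \code{threeD} and \code{twoD}, both
#'   [ObserverAgreementResult-class].
#' @export
simulateObserverStudy <- function(studies, organ, nObservers = 3L,
                                  magnitude = 1L, seed = 1L, tRefH = 24,
                                  permutations = 0L) {
  if (nObservers < 2L) stop("need >= 2 observers")
  single <- is(studies, "StudyDataset")
  if (single) studies <- list(studies)

  extract <- function(study, obsSeeds) {
    ph <- study@phantom
    mask3 <- ph@masks[[organ]]
    if (is.null(mask3)) stop(sprintf("no organ '%s' in study", organ))
    st <- study@spectTimesH
    tt <- if (length(st)) st[which.min(abs(st - tRefH))] else
      stop("study has no SPECT volume for 3D extraction")
    vol <- study@spect[[as.character(tt)]]
    i2 <- which.min(abs(study@timesH - tt))
    gm <- .gmImage(study, i2)
    mask2 <- projectVoi(mask3)
    # the 2D value is what the planar workflow extracts: background-corrected
    # ROI counts (band and weighting factor of the unperturbed organ)
    wf <- thicknessFromMasks(ph, organ)@wf
    bodyFoot <- apply(ph@body, c(1L, 3L), any)
    forb <- Reduce(`|`, lapply(ph@masks, projectVoi)) | .syringeBlock(study)
    band <- placeBackgroundRoi(mask2, forb, bodyFoot)
    bgRate <- sum(gm[band]) / sum(band)
    vapplyRes <- lapply(obsSeeds, function(s) {
      pm3 <- .observerPerturb(mask3, magnitude, s)
      pm2 <- .observerPerturb(mask2, magnitude, s + 1L)
      c(sum(vol[pm3]),
        correctBackground(sum(gm[pm2]), sum(pm2), bgRate, 1, wf)$counts)
    })
    do.call(rbind, vapplyRes)
  }

  counts3 <- matrix(0, nObservers, length(studies))
  counts2 <- matrix(0, nObservers, length(studies))
  if (single && length(studies) == 1L && length(studies[[1L]]@timesH) > 1L) {
    # items = time points of the single study
    study <- studies[[1L]]
    nt <- length(study@timesH)
    counts3 <- matrix(0, nObservers, nt)
    counts2 <- matrix(0, nObservers, nt)
    ph <- study@phantom
    mask3 <- ph@masks[[organ]]
    mask2 <- projectVoi(mask3)
    for (o in seq_len(nObservers)) {
      s <- seed + 1000L * o
      pm3 <- .observerPerturb(mask3, magnitude, s)
      pm2 <- .observerPerturb(mask2, magnitude, s + 1L)
      for (i in seq_len(nt)) {
        tt <- as.character(study@timesH[i])
        if (tt %in% names(study@spect))
          counts3[o, i] <- sum(study@spect[[tt]][pm3])
        counts2[o, i] <- sum(.gmImage(study, i)[pm2])
      }
    }
    keep <- study@timesH %in% study@spectTimesH
    counts3 <- counts3[, keep, drop = FALSE]
  } else {
    # each observer keeps one systematic delineation style across all items
    obsSeeds <- as.list(seed + 1000L * seq_len(nObservers))
    for (k in seq_along(studies)) {
      res <- extract(studies[[k]], obsSeeds)
      counts3[, k] <- res[, 1L]
      counts2[, k] <- res[, 2L]
    }
  }
  list(threeD = kendallsW(counts3, permutations, seed),
       twoD = kendallsW(counts2, permutations, seed + 1L))
}

.observerPerturb <- function(mask, magnitude, seed) {
  if (magnitude == 0) return(mask)
  .withLocalSeed(seed, {
    nd <- length(dim(mask))
    sh <- sample(seq(-magnitude, magnitude), nd, replace = TRUE)
    m <- perturbRoi(mask, "shift", magnitude, shift = sh)
    grow <- sample(c(-1L, 0L, 1L), 1L)
    if (grow > 0) m <- perturbRoi(m, "dilate", 1L)
    if (grow < 0) m <- tryCatch(perturbRoi(m, "erode", 1L),
                                error = function(e) m)
    m
  })
}

# ---------------------------------------------------------------------------
# Bundled phantoms and cohorts
# ---------------------------------------------------------------------------

#' Reference abdominal-thoracic phantom
#'
#' The bundled "clinic-like" phantom: a soft-tissue body slab carrying
#' liver (with one spherical tumour lesion), both kidneys, spleen and lungs,
#' with the liver superimposed over the right kidney in anterior-posterior
#' projection -- the constellation that makes planar kidney quantification
#' overestimate. Kinetic defaults are chosen so true residence times sit in
#' the clinically reported range (kidneys ~1.3 h each, liver ~28 h,
#' spleen ~2.4 h, lungs ~0.5 h, tumour DpA ~2.7 Gy/GBq at ~20 g).
#'
#' @param organScale optional named numeric vector of per-organ size scale
#'   factors (cohort jitter; keep within about 0.95..1.05).
#' @param uptakeScale optional named numeric vector of per-organ uptake
#'   fraction scale factors.
#' @param bioScale optional named numeric vector of per-organ biological
#'   half-life scale factors.
#' @param liverShift length-3 numeric, mm: rigid displacement of the liver
#'   (and the tumour inside it), emulating inter-patient variation of the
#'   liver/kidney juxtaposition; keep x within +/- 4 mm and z within
#'   -4..0 mm so organs stay 3D-disjoint.
#' @return a [PhantomSpec-class] (grid 44 x 24 x 72 voxels of 5 mm).
#' @export
referencePhantomSpec <- function(organScale = NULL, uptakeScale = NULL,
                                 bioScale = NULL, liverShift = c(0, 0, 0)) {
  base <- list(
    liver        = list(shape = "ellipsoid", center = c(70, 50, 220),
                        semi = c(50, 32, 45), density = 1.06, f = 0.2,
                        tbio = 250, tum = FALSE, host = NA_character_),
    tumour       = list(shape = "sphere", center = c(70, 50, 235),
                        semi = c(17, 17, 17), density = 1.06, f = 0.0046,
                        tbio = 300, tum = TRUE, host = "liver"),
    kidney_right = list(shape = "ellipsoid", center = c(80, 95, 190),
                        semi = c(16, 12, 30), density = 1.05, f = 0.018,
                        tbio = 70, tum = FALSE, host = NA_character_),
    kidney_left  = list(shape = "ellipsoid", center = c(150, 95, 185),
                        semi = c(16, 12, 30), density = 1.05, f = 0.018,
                        tbio = 70, tum = FALSE, host = NA_character_),
    spleen       = list(shape = "ellipsoid", center = c(160, 70, 240),
                        semi = c(20, 18, 28), density = 1.06, f = 0.027,
                        tbio = 100, tum = FALSE, host = NA_character_),
    lungs        = list(shape = "ellipsoid", center = c(110, 55, 306),
                        semi = c(70, 32, 36), density = 0.26, f = 0.011,
                        tbio = 40, tum = FALSE, host = NA_character_))
  base$liver$center <- base$liver$center + liverShift
  base$tumour$center <- base$tumour$center + liverShift
  sc <- function(v, nm, def = 1) if (!is.null(v) && nm %in% names(v)) v[[nm]] else def
  organs <- lapply(names(base), function(nm) {
    b <- base[[nm]]
    organSpec(nm, b$shape, b$center, b$semi * sc(organScale, nm),
              density = b$density,
              uptakeFraction = b$f * sc(uptakeScale, nm),
              bioHalfLife = b$tbio * sc(bioScale, nm),
              isTumour = b$tum, hostOrgan = b$host)
  })
  phantomSpec(c(44, 24, 72), 5, organs, bodyShape = "box",
              bodyCenter = c(110, 60, 190), bodySemiAxes = c(90, 50, 160),
              backgroundUptake = 0.5, backgroundHalfLife = 100)
}

#' Attenuation-free, blur-free phantom for the no-physics limit
#'
#' Two well-separated organs plus background on a box body with zero
#' attenuation: in this limit the three scenarios must agree on every organ
#' dose.
#'
#' @return a [PhantomSpec-class].
#' @export
noPhysicsPhantomSpec <- function() {
  organs <- list(
    organSpec("organ_a", "ellipsoid", c(60, 60, 80), c(24, 16, 28),
              density = 1.05, uptakeFraction = 0.05, bioHalfLife = 80),
    organSpec("organ_b", "ellipsoid", c(140, 60, 180), c(28, 20, 30),
              density = 1.06, uptakeFraction = 0.1, bioHalfLife = 200))
  phantomSpec(c(40, 24, 52), 5, organs, bodyShape = "box",
              bodyCenter = c(100, 60, 140), bodySemiAxes = c(80, 50, 110),
              backgroundUptake = 0.3, backgroundHalfLife = 100,
              muSoft = 0, muLung = 0)
}

#' Default acquisition protocol of the reference phantom
#'
#' Five planar time points at 4, 24, 48, 72 and 168 h p.i. with SPECT at
#' every time point, 10 mm SPECT PSF, 8 mm planar PSF, noise off.
#'
#' @param seed integer seed.
#' @param noise Poisson noise on planar counts?
#' @return an [AcquisitionSpec-class].
#' @export
referenceAcquisitionSpec <- function(seed = 1L, noise = FALSE)
  acquisitionSpec(timePoints = c(4, 24, 48, 72, 168), spectFwhm = 10,
                  planarFwhm = 8, noise = noise, seed = seed)

#' Simulate a cohort of jittered reference studies
#'
#' Draws \code{n} patient-equivalent studies from the reference phantom with
#' seeded jitter of organ sizes (+/- 5\%), uptake fractions (+/- 20\%),
#' biological half-lives (+/- 20\%) and administered activity
#' (normal, 7.2 +/- 0.4 GBq), because paired scenario statistics need a
#' cohort that single phantoms cannot provide.
#'
#' @param n number of studies.
#' @param seed integer master seed.
#' @param noise Poisson noise on planar counts?
#' @return named list of [StudyDataset-class].
#' @export
simulateCohort <- function(n, seed = 1L, noise = FALSE) {
  organs <- c("liver", "tumour", "kidney_right", "kidney_left", "spleen",
              "lungs")
  .withLocalSeed(seed, {
    studies <- list()
    for (k in seq_len(n)) {
      os <- setNames(stats::runif(length(organs), 0.95, 1.05), organs)
      us <- setNames(stats::runif(length(organs), 0.8, 1.2), organs)
      bs <- setNames(stats::runif(length(organs), 0.8, 1.2), organs)
      ls <- c(stats::runif(1, -4, 4), 0, stats::runif(1, -4, 0))
      adm <- max(stats::rnorm(1, 7.2, 0.4), 5)
      subSeed <- (seed * 1000L + k) %% .Machine$integer.max
      studies[[sprintf("study%02d", k)]] <- simulateStudy(
        referencePhantomSpec(os, us, bs, liverShift = ls),
        referenceAcquisitionSpec(seed = subSeed, noise = noise),
        administrationRecord(adm))
    }
    studies
  })
}
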