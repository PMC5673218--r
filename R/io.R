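# Study dataset readers/writers (NIfTI volumes + JSON manifest), report
# writers (CSV/JSON) and run-configuration validation.

.organToList <- function(o)
  list(name = o@name, shape = o@shape, center = o@center,
       semiAxes = o@semiAxes, density = o@density,
       uptakeFraction = o@uptakeFraction,
       bioHalfLife = if (is.finite(o@bioHalfLife)) o@bioHalfLife else "Inf",
       isTumour = o@isTumour, hostOrgan = o@hostOrgan)

.organFromList <- function(l)
  organSpec(l$name, l$shape, unlist(l$center), unlist(l$semiAxes),
            density = l$density, uptakeFraction = l$uptakeFraction,
            bioHalfLife = if (identical(l$bioHalfLife, "Inf")) Inf
                          else as.numeric(l$bioHalfLife),
            isTumour = isTRUE(l$isTumour),
            hostOrgan = if (is.null(l$hostOrgan) || is.na(l$hostOrgan))
              NA_character_ else l$hostOrgan)

#' Write a StudyDataset to a directory
#'
#' Volumes and masks go to NIfTI (planar count images as 2D NIfTI, SPECT and
#' tissue volumes as 3D NIfTI, organ masks as one integer label image); all
#' scalar metadata, the organ specifications, the administration/calibration
#' records and the truth table go to \code{manifest.json}.
#'
#' @param study a [StudyDataset-class].
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ph <- study@phantom
  spec <- ph@spec
  wn <- function(x, f) RNifti::writeNifti(x, file.path(dir, f))

  files <- list(anterior = character(), posterior = character(),
                spect = character())
  for (i in seq_along(study@timesH)) {
    t <- study@timesH[i]
    fa <- sprintf("planar_anterior_%03dh.nii.gz", round(t))
    fp <- sprintf("planar_posterior_%03dh.nii.gz", round(t))
    wn(study@anterior[[i]], fa)
    wn(study@posterior[[i]], fp)
    files$anterior <- c(files$anterior, fa)
    files$posterior <- c(files$posterior, fp)
  }
  for (tt in names(study@spect)) {
    fs <- sprintf("spect_%03dh.nii.gz", round(as.numeric(tt)))
    wn(study@spect[[tt]], fs)
    files$spect <- c(files$spect, fs)
  }
  labels <- array(0L, dim(ph@body))
  for (i in seq_along(ph@masks)) labels[ph@masks[[i]]] <- i
  wn(labels, "masks.nii.gz")
  wn(ph@body * 1L, "body.nii.gz")
  wn(ph@density, "density.nii.gz")
  wn(ph@attenuation, "attenuation.nii.gz")

  acq <- study@acquisition
  manifest <- list(
    times_h = study@timesH, spect_times_h = study@spectTimesH,
    files = files,
    voxel_size_mm = spec@voxelSize, grid = spec@dim,
    body = list(shape = spec@bodyShape, center = spec@bodyCenter,
                semiAxes = spec@bodySemiAxes),
    background = list(uptake = spec@backgroundUptake,
                      halfLife = if (is.finite(spec@backgroundHalfLife))
                        spec@backgroundHalfLife else "Inf"),
    attenuation_cm = list(soft = spec@muSoft, lung = spec@muLung),
    organs = lapply(spec@organs, .organToList),
    mask_labels = as.list(setNames(seq_along(ph@masks), names(ph@masks))),
    administration = list(activityGBq = study@admin@activityGBq,
                          time0 = study@admin@time0),
    calibration = list(activityMBq = study@calibration@activityMBq,
                       refTimeH = study@calibration@refTimeH,
                       volumeML = study@calibration@volumeML,
                       location = study@calibration@location,
                       durationS = study@calibration@durationS),
    acquisition = list(timePoints = acq@timePoints,
                       spectTimes = acq@spectTimes,
                       physicalHalfLife = acq@physicalHalfLife,
                       planarSensitivity = acq@planarSensitivity,
                       planarDuration = acq@planarDuration,
                       spectFwhm = acq@spectFwhm, planarFwhm = acq@planarFwhm,
                       noise = acq@noise, spectNoiseSd = acq@spectNoiseSd,
                       seed = acq@seed),
    truth = study@truth)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a StudyDataset from a directory
#'
#' Reconstructs the study written by [writeStudy()], enforcing geometry
#' consistency. A SPECT frame listed in the manifest but missing on disk is
#' dropped with a warning, and the returned study carries a
#' \code{"capabilities"} attribute marking it planar-only capable when SPECT
#' coverage is incomplete.
#'
#' @param dir study directory containing \code{manifest.json}.
#' @return a [StudyDataset-class].
#' @export
readStudy <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop(sprintf("no manifest.json in '%s'", dir))
  man <- jsonlite::fromJSON(mf, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  times <- as.numeric(man$times_h)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("manifest times_h must be >= 2 strictly increasing values")

  rd <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop(sprintf("missing file '%s'", f))
    v <- RNifti::readNifti(p)
    array(as.numeric(v), dim(v))
  }

  organs <- lapply(man$organs, .organFromList)
  spec <- phantomSpec(unlist(man$grid), unlist(man$voxel_size_mm), organs,
                      bodyShape = man$body$shape,
                      bodyCenter = unlist(man$body$center),
                      bodySemiAxes = unlist(man$body$semiAxes),
                      backgroundUptake = man$background$uptake,
                      backgroundHalfLife =
                        if (identical(man$background$halfLife, "Inf")) Inf
                        else as.numeric(man$background$halfLife),
                      muSoft = man$attenuation_cm$soft,
                      muLung = man$attenuation_cm$lung)

  labels <- rd("masks.nii.gz")
  body <- rd("body.nii.gz") > 0
  masks <- lapply(man$mask_labels, function(code) labels == code)
  ph <- new("VoxelPhantom", spec = spec, masks = masks, body = body,
            density = rd("density.nii.gz"),
            attenuation = rd("attenuation.nii.gz"))

  anterior <- lapply(man$files$anterior, function(f) {
    img <- rd(f); matrix(img, dim(img)[1L], dim(img)[2L])
  })
  posterior <- lapply(man$files$posterior, function(f) {
    img <- rd(f); matrix(img, dim(img)[1L], dim(img)[2L])
  })

  spectTimes <- as.numeric(man$spect_times_h)
  spect <- list()
  keep <- logical(length(spectTimes))
  for (i in seq_along(spectTimes)) {
    f <- man$files$spect[i]
    p <- file.path(dir, f)
    if (file.exists(p)) {
      spect[[as.character(spectTimes[i])]] <- rd(f)
      keep[i] <- TRUE
    } else {
      warning(sprintf("SPECT frame '%s' missing; study loads planar-only for %g h",
                      f, spectTimes[i]))
    }
  }

  acq <- man$acquisition
  truth <- if (is.null(man$truth) || !length(man$truth)) NULL else {
    df <- do.call(rbind, lapply(man$truth, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    rownames(df) <- NULL
    df
  }

  study <- new("StudyDataset", timesH = times, anterior = anterior,
               posterior = posterior, spectTimesH = spectTimes[keep],
               spect = spect, phantom = ph,
               admin = administrationRecord(man$administration$activityGBq,
                                            man$administration$time0),
               calibration = calibrationStandard(
                 man$calibration$activityMBq, man$calibration$refTimeH,
                 man$calibration$volumeML, unlist(man$calibration$location),
                 man$calibration$durationS),
               acquisition = acquisitionSpec(
                 unlist(acq$timePoints), unlist(acq$spectTimes),
                 acq$physicalHalfLife, acq$planarSensitivity,
                 acq$planarDuration, acq$spectFwhm, acq$planarFwhm,
                 isTRUE(acq$noise), acq$spectNoiseSd, acq$seed),
               truth = truth)
  attr(study, "capabilities") <- c(
    planar = TRUE,
    multi_spect = all(times %in% spectTimes[keep]))
  study
}

#' Write scenario reports to a directory
#'
#' Writes \code{doses.csv} and \code{residence_times.csv} (stable column
#' contract across runs), optionally \code{comparison.json}, and a run
#' \code{run_manifest.json} with the seed and a config hash. Outputs are
#' deterministic: the same results produce byte-identical CSVs.
#'
#' @param results a [ScenarioResult-class], or a (possibly named) list of
#'   them.
#' @param dir output directory.
#' @param comparison optional [ScenarioComparison-class].
#' @param config optional validated configuration list (hashed into the
#'   manifest).
#' @param seed optional integer seed recorded in the manifest.
#' @return character vector of files written, invisibly.
#' @export
writeReports <- function(results, dir, comparison = NULL, config = NULL,
                         seed = NULL) {
  if (is(results, "ScenarioResult")) results <- list(results)
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("cannot create output directory '%s'", dir))
  doses <- do.call(rbind, c(lapply(results, slot, name = "doses"),
                            list(make.row.names = FALSE)))
  rts <- do.call(rbind, c(lapply(results, residenceTimes),
                          list(make.row.names = FALSE)))
  f1 <- file.path(dir, "doses.csv")
  f2 <- file.path(dir, "residence_times.csv")
  utils::write.csv(doses, f1, row.names = FALSE)
  utils::write.csv(rts, f2, row.names = FALSE)
  written <- c(f1, f2)

  if (!is.null(comparison)) {
    f3 <- file.path(dir, "comparison.json")
    jsonlite::write_json(list(ratios = comparison@ratios,
                              friedman = comparison@friedman,
                              wilcoxon = comparison@wilcoxon),
                         f3, auto_unbox = TRUE, digits = NA)
    written <- c(written, f3)
  }

  cfgHash <- NA_character_
  if (!is.null(config)) {
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(config, tmp)
    cfgHash <- unname(tools::md5sum(tmp))
    unlink(tmp)
  }
  fm <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(list(seed = seed, config_md5 = cfgHash,
                            scenarios = vapply(results, slot, character(1),
                                               name = "scenario")),
                       fm, auto_unbox = TRUE, digits = NA)
  invisible(c(written, fm))
}

.configDefaults <- function() list(
  physical_half_life_h = 159.528,
  electron_energy_mev = 0.1479,
  mu_soft_cm = 0.137,
  mu_lung_cm = 0.04,
  planar_sensitivity_cps_per_mbq = 10,
  planar_duration_s = 300,
  spect_fwhm_mm = 10,
  planar_fwhm_mm = 8,
  noise = FALSE,
  seed = 1L,
  scenario = "all",
  t_ref_h = 24,
  administered_gbq = 7.2)

#' Validate and normalise a run configuration
#'
#' Fills defaults and normalises units to (hours, MBq/GBq, mm, g, Gy).
#' \code{half_life_days} is accepted and converted to
#' \code{physical_half_life_h}. Unknown keys are an error -- typos never
#' pass silently -- as are non-positive physics constants.
#'
#' @param cfg a named list, a YAML file path, or NULL/empty for all
#'   defaults.
#' @return a named list with every key of the default configuration.
#' @examples
#' validateConfig(list(half_life_days = 6.647))$physical_half_life_h
#' @export
validateConfig <- function(cfg = NULL) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config must be a list, a YAML path or NULL")
  def <- .configDefaults()
  if ("half_life_days" %in% names(cfg)) {
    cfg$physical_half_life_h <- cfg$half_life_days * 24
    cfg$half_life_days <- NULL
  }
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  out <- utils::modifyList(def, cfg)
  numPos <- c("physical_half_life_h", "electron_energy_mev",
              "planar_sensitivity_cps_per_mbq", "planar_duration_s",
              "administered_gbq")
  for (k in numPos)
    if (!is.numeric(out[[k]]) || out[[k]] <= 0)
      stop(sprintf("config key '%s' must be a positive number", k))
  numNonneg <- c("mu_soft_cm", "mu_lung_cm", "spect_fwhm_mm",
                 "planar_fwhm_mm")
  for (k in numNonneg)
    if (!is.numeric(out[[k]]) || out[[k]] < 0)
      stop(sprintf("config key '%s' must be >= 0", k))
  if (!out$scenario %in% c("all", "multi_spect", "planar", "hybrid"))
    stop("scenario must be all, multi_spect, planar or hybrid")
  out$seed <- as.integer(out$seed)
  out
}
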