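#' Organ names of a phantom or study
#'
#' @param x a [VoxelPhantom-class], [StudyDataset-class] or
#'   [PhantomSpec-class].
#' @return character vector of organ identifiers.
#' @export
setGeneric("organNames", function(x) standardGeneric("organNames"))

#' @rdname organNames
#' @export
setMethod("organNames", "PhantomSpec", function(x)
  vapply(x@organs, slot, character(1), name = "name"))

#' @rdname organNames
#' @export
setMethod("organNames", "VoxelPhantom", function(x) names(x@masks))

#' @rdname organNames
#' @export
setMethod("organNames", "StudyDataset", function(x) names(x@phantom@masks))

#' Per-organ dose table of a scenario result or comparison
#'
#' @param x a [ScenarioResult-class] or [ScenarioComparison-class].
#' @return a data.frame; for a \code{ScenarioResult} the per-organ doses, for
#'   a \code{ScenarioComparison} the long per-study DpA table.
#' @export
setGeneric("doseTable", function(x) standardGeneric("doseTable"))

#' @rdname doseTable
#' @export
setMethod("doseTable", "ScenarioResult", function(x) x@doses)

#' @rdname doseTable
#' @export
setMethod("doseTable", "ScenarioComparison", function(x) x@doses)

#' Residence times of a scenario result
#'
#' @param x a [ScenarioResult-class].
#' @return data.frame with columns organ, method, tau_h.
#' @export
setGeneric("residenceTimes", function(x) standardGeneric("residenceTimes"))

#' @rdname residenceTimes
#' @export
setMethod("residenceTimes", "ScenarioResult", function(x)
  data.frame(organ = x@doses$organ, method = x@scenario,
             tau_h = x@doses$tau_h))

#' Ground-truth kinetics record of a simulated study
#'
#' @param x a [StudyDataset-class].
#' @return data.frame (organ, f, lambda_eff_per_h, tau_h, mass_g, dose_Gy,
#'   dpa_Gy_per_GBq) or NULL for imported studies without truth.
#' @export
setGeneric("truthRecord", function(x) standardGeneric("truthRecord"))

#' @rdname truthRecord
#' @export
setMethod("truthRecord", "StudyDataset", function(x) x@truth)

#' Planar time points of a study
#'
#' @param x a [StudyDataset-class].
#' @return numeric vector, hours post injection.
#' @export
setGeneric("studyTimes", function(x) standardGeneric("studyTimes"))

#' @rdname studyTimes
#' @export
setMethod("studyTimes", "StudyDataset", function(x) x@timesH)

#' Median-ratio table of a comparison
#'
#' @param x a [ScenarioComparison-class].
#' @return data.frame with per-scenario medians and hybrid/multi,
#'   planar/multi median ratios.
#' @export
setGeneric("ratioTable", function(x) standardGeneric("ratioTable"))

#' @rdname ratioTable
#' @export
setMethod("ratioTable", "ScenarioComparison", function(x) x@ratios)

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "OrganSpec", function(object) {
  cat(sprintf("OrganSpec '%s' (%s)%s\n", object@name, object@shape,
              if (object@isTumour) " [tumour]" else ""))
  cat(sprintf("  centre %s mm, semi-axes %s mm, density %.2f g/mL\n",
              paste(object@center, collapse = ", "),
              paste(object@semiAxes, collapse = ", "), object@density))
  cat(sprintf("  uptake fraction %.4g, biological half-life %s h\n",
              object@uptakeFraction,
              if (is.finite(object@bioHalfLife))
                format(object@bioHalfLife) else "Inf"))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s voxels at %s mm, %d organ(s), background f = %.3g\n",
              paste(object@dim, collapse = "x"),
              paste(object@voxelSize, collapse = "x"),
              length(object@organs), object@backgroundUptake))
})

setMethod("show", "VoxelPhantom", function(object) {
  cat(sprintf("VoxelPhantom: grid %s, voxel %s mm\n",
              paste(dim(object@body), collapse = "x"),
              paste(object@spec@voxelSize, collapse = "x")))
  vox_ml <- prod(object@spec@voxelSize) / 1000
  for (nm in names(object@masks))
    cat(sprintf("  %-14s %6d voxels (%.1f mL)\n", nm,
                sum(object@masks[[nm]]), sum(object@masks[[nm]]) * vox_ml))
})

setMethod("show", "StudyDataset", function(object) {
  cat(sprintf("StudyDataset: %d planar time points (%s h), SPECT at %s h\n",
              length(object@timesH), paste(object@timesH, collapse = ", "),
              if (length(object@spectTimesH))
                paste(object@spectTimesH, collapse = ", ") else "none"))
  cat(sprintf("  administered %.2f GBq; %d organ masks; truth %s\n",
              object@admin@activityGBq, length(object@phantom@masks),
              if (is.null(object@truth)) "absent" else "present"))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf(
    "FitResult '%s' (%s): A0 = %.4g MBq, lambda = %.5g /h (T_eff = %.3g h), R^2 = %.4f\n",
    object@organ, object@method, object@A0, object@lambda,
    log(2) / object@lambda, object@r2))
})

setMethod("show", "ScenarioResult", function(object) {
  cat(sprintf("ScenarioResult '%s': %d organ(s)\n", object@scenario,
              nrow(object@doses)))
  print(object@doses[, c("organ", "tau_h", "mass_g", "dose_Gy",
                         "dpa_Gy_per_GBq")], row.names = FALSE, digits = 4)
})

setMethod("show", "ScenarioComparison", function(object) {
  cat(sprintf("ScenarioComparison: %d studies, %d organ(s)\n",
              length(unique(object@doses$study)),
              length(unique(object@doses$organ))))
  print(object@ratios, row.names = FALSE, digits = 3)
})

setMethod("show", "ObserverAgreementResult", function(object) {
  cat(sprintf(
    "Kendall's W = %.3f (%d observers x %d items), chi-square p = %.4g%s\n",
    object@W, object@nObservers, object@nItems, object@pChisq,
    if (is.na(object@pPermutation)) ""
    else sprintf(", permutation p = %.4g", object@pPermutation)))
})
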