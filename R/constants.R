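#' Physics and reporting constants for 177Lu dosimetry
#'
#' Package-level defaults used throughout the pipeline. All of them are plain
#' arguments on the functions that consume them, so every value can be
#' overridden per call; these are the documented defaults.
#'
#' @details
#' \describe{
#'   \item{\code{luPhysicalHalfLifeHours}}{Physical half-life of 177Lu,
#'     6.647 d = 159.528 h (standard decay data).}
#'   \item{\code{luElectronEnergyMeV}}{Mean electron (beta + conversion/Auger)
#'     energy emitted per 177Lu decay, 0.1479 MeV, used by the local
#'     electron-deposition dose model.}
#'   \item{\code{attenuationSoftTissue}}{Linear attenuation coefficient of
#'     water-like soft tissue at 208 keV, 0.137 cm^-1.}
#'   \item{\code{attenuationLung}}{Linear attenuation coefficient of inflated
#'     lung at 208 keV, 0.04 cm^-1.}
#'   \item{\code{organDensities}}{Standardised tissue densities in g/mL used
#'     to turn CT-derived organ volumes into masses: kidney 1.05, liver 1.06,
#'     spleen 1.06, lungs 0.26; tumour lesions use the liver value.}
#' }
#' @return \code{luConstants()} returns a named list of the defaults above.
#' @examples
#' luConstants()$physical_half_life_h
#' @export
luConstants <- function() {
  list(
    physical_half_life_h = 159.528,   # 6.647 d
    electron_energy_mev  = 0.1479,
    mu_soft_cm           = 0.137,     # 208 keV, water-like tissue
    mu_lung_cm           = 0.04,
    mu_air_cm            = 0.0,
    densities_g_per_ml   = c(kidney = 1.05, liver = 1.06, spleen = 1.06,
                             lungs = 0.26, tumour = 1.06, soft = 1.03),
    decays_per_gbq_h     = 3.6e12,
    joule_per_mev        = 1.602176634e-13
  )
}

# internal shorthands
.LU_THALF_H <- 159.528
.LU_DELTA_E <- 0.1479
.MEV_TO_J <- 1.602176634e-13
.DECAYS_PER_GBQ_H <- 3.6e12
.FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))
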