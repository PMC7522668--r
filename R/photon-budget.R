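#' ANSI skin maximum permissible exposure table
#'
#' The CW skin-exposure irradiance limits used for near-infrared diffuse
#' optics: 0.27 W/cm^2 at 765 nm, 0.29 at 785 nm, 0.40 at 850 nm, and 1.07
#' W/cm^2 throughout the 1000-1400 nm band. These are regulatory constants;
#' wavelengths not covered raise an error rather than being interpolated.
#'
#' @return Tibble with `wavelength_nm` (NA for the band entry), `band_lo_nm`,
#'   `band_hi_nm`, `mpe_W_cm2`.
#' @export
mpe_table <- function() {
  tibble::tribble(
    ~wavelength_nm, ~band_lo_nm, ~band_hi_nm, ~mpe_W_cm2,
    765,  NA,   NA,   0.27,
    785,  NA,   NA,   0.29,
    850,  NA,   NA,   0.40,
    NA,   1000, 1400, 1.07)
}

mpe_at <- function(wavelength_nm) {
  tab <- mpe_table()
  vapply(wavelength_nm, function(wl) {
    i <- which(!is.na(tab$wavelength_nm) & tab$wavelength_nm == wl)
    if (length(i) == 1) return(tab$mpe_W_cm2[i])
    j <- which(!is.na(tab$band_lo_nm) & wl >= tab$band_lo_nm & wl <= tab$band_hi_nm)
    if (length(j) == 1) return(tab$mpe_W_cm2[j])
    abort(sprintf("no MPE entry for %g nm; refusing to interpolate a regulatory limit", wl))
  }, numeric(1))
}

#' Permitted illumination power under the skin-exposure limit
#'
#' MPE irradiance times the standard averaging aperture area. For diffuse
#' illumination spots above 1 mm diameter a 3.5-mm aperture applies, which is
#' the default.
#'
#' @param wavelength_nm Wavelength(s) with an MPE entry.
#' @param aperture_cm Aperture diameter in cm (default 0.35).
#' @return Permitted power in mW.
#' @examples
#' permitted_power(c(765, 785, 850, 1064))
#' @export
permitted_power <- function(wavelength_nm, aperture_cm = 0.35) {
  if (any(aperture_cm <= 0)) abort("aperture must be > 0")
  mpe_at(wavelength_nm) * pi * (aperture_cm / 2)^2 * 1000
}

#' Photon emission rate of a source
#'
#' `power * lambda / (h c)`: photons per second delivered at a given power.
#' Longer wavelengths deliver proportionally more photons per unit energy.
#'
#' @param power_W Optical power in watts (>= 0).
#' @param wavelength_nm Wavelength in nm.
#' @return Photons per second.
#' @examples
#' photon_rate(26e-3, 765)
#' @export
photon_rate <- function(power_W, wavelength_nm) {
  if (any(power_W < 0)) abort("power must be >= 0")
  if (any(wavelength_nm <= 0)) abort("wavelength must be > 0")
  power_W * (wavelength_nm * 1e-9) / (.h_planck * .c_light)
}

#' Detected-intensity ratio from effective attenuation
#'
#' Ratio of diffusely detected intensities at two wavelengths given their
#' effective attenuation coefficients, using the normalized-exponent form
#' `exp(((mueff_ref - mueff_new) / mueff_ref) * r)`. Note the exponent is the
#' fractional attenuation difference multiplied by the source-detector
#' separation `r` expressed in cm; this fixes the convention.
#'
#' @param mueff_ref Attenuation at the reference (shorter) wavelength, cm^-1, > 0.
#' @param mueff_new Attenuation at the comparison wavelength, cm^-1.
#' @param r_cm Source-detector separation in cm (default 3).
#' @return Intensity ratio (dimensionless, > 0); 1 when attenuations match
#'   or `r_cm = 0`.
#' @examples
#' detected_intensity_ratio(2.2, 1.7, 3)
#' @export
detected_intensity_ratio <- function(mueff_ref, mueff_new, r_cm = 3) {
  if (any(mueff_ref <= 0)) abort("mueff_ref must be > 0")
  if (any(r_cm < 0)) abort("r_cm must be >= 0")
  exp(((mueff_ref - mueff_new) / mueff_ref) * r_cm)
}

#' Photon-budget report versus a long reference wavelength
#'
#' Quantifies, per wavelength, the three multiplicative photon-count
#' advantages of the reference wavelength (default 1064 nm): the permitted
#' power ratio under skin-exposure limits, the photons-per-unit-energy ratio,
#' and the detected-intensity ratio from the lower effective attenuation.
#' `combined_gain` is their product.
#'
#' @param mueff Data frame with columns `wavelength_nm` and `mueff_mean`
#'   (default [reference_population_properties()]).
#' @param reference_nm Reference wavelength (default 1064).
#' @param wavelength_nm Comparison wavelengths (default 765, 785, 850).
#' @param r_cm Source-detector separation, cm.
#' @param aperture_cm MPE averaging-aperture diameter, cm.
#' @return Tibble, one row per comparison wavelength, with the permitted
#'   powers (mW), photon emission rates at those powers, the three gain
#'   factors, and `combined_gain`.
#' @examples
#' photon_budget()
#' @export
photon_budget <- function(mueff = reference_population_properties(),
                          reference_nm = 1064,
                          wavelength_nm = c(765, 785, 850),
                          r_cm = 3, aperture_cm = 0.35) {
  mu <- function(wl) {
    i <- match(wl, mueff$wavelength_nm)
    if (any(is.na(i))) abort("mueff table lacks a needed wavelength")
    mueff$mueff_mean[i]
  }
  p_ref <- permitted_power(reference_nm, aperture_cm)
  purrr::map_dfr(wavelength_nm, function(wl) {
    p <- permitted_power(wl, aperture_cm)
    energy_ratio <- p_ref / p
    photons_per_energy_ratio <- reference_nm / wl
    intensity_ratio <- detected_intensity_ratio(mu(wl), mu(reference_nm), r_cm)
    tibble::tibble(
      wavelength_nm = wl, reference_nm = reference_nm,
      permitted_power_mW = p, reference_power_mW = p_ref,
      photon_rate_cps = photon_rate(p / 1000, wl),
      energy_ratio = energy_ratio,
      photons_per_energy_ratio = photons_per_energy_ratio,
      intensity_ratio = intensity_ratio,
      combined_gain = energy_ratio * photons_per_energy_ratio * intensity_ratio)
  })
}
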