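#' Scale presets for the three end-to-end studies
#'
#' `"full"` matches the complete protocol (150,000 population samples, a 1%
#' deep-flow grid, 1e8 transport photons); `"desk"` is the scaled-down
#' version used for routine runs and testing (20,000 samples, 5% grid, 1e7
#' photons).
#'
#' @param scale `"desk"` or `"full"`.
#' @return Named list of study sizes.
#' @export
study_preset <- function(scale = c("desk", "full")) {
  scale <- match.arg(scale)
  if (scale == "full") {
    list(scale = "full", n_population = 150000,
         change_pct = seq(1, 100, by = 1), n_photons = 1e8)
  } else {
    list(scale = "desk", n_population = 20000,
         change_pct = seq(5, 100, by = 5), n_photons = 1e7)
  }
}

#' Population study driver: sampled optical properties vs reference values
#'
#' Runs [sample_tissue_population()] (N from the preset; note the pairwise
#' comparison uses the full N = 150,000 protocol on `scale = "full"`) and
#' joins the per-wavelength summary against the bundled reference values
#' from [reference_population_properties()], reporting deviations.
#'
#' @param scale `"desk"` or `"full"`.
#' @param seed Seed for the population draw.
#' @param table Extinction table.
#' @param ... Passed to [sample_tissue_population()].
#' @return List: `population` (the `dcsim_population`), `comparison`
#'   (tibble of sampled vs reference means with deviations).
#' @examples
#' st <- run_population_study(seed = 1)
#' st$comparison
#' @export
run_population_study <- function(scale = c("desk", "full"), seed = 1,
                                 table = extinction_table(), ...) {
  preset <- study_preset(match.arg(scale))
  pop <- sample_tissue_population(n = preset$n_population, seed = seed,
                                  table = table, ...)
  ref <- reference_population_properties()
  comparison <- dplyr::left_join(
    dplyr::select(pop$summary, "wavelength_nm", "mua_mean", "musp_mean",
                  "mueff_mean"),
    dplyr::select(ref, "wavelength_nm",
                  ref_mua = "mua_mean", ref_musp = "musp_mean",
                  ref_mueff = "mueff_mean"),
    by = "wavelength_nm")
  comparison <- dplyr::mutate(
    comparison,
    mua_dev = .data$mua_mean - .data$ref_mua,
    musp_dev = .data$musp_mean - .data$ref_musp,
    mueff_dev = .data$mueff_mean - .data$ref_mueff)
  list(population = pop, comparison = comparison)
}

#' Homogeneous g2 study driver: clean and noisy curves across wavelengths
#'
#' Simulates semi-infinite g2 curves at a common BFi for each wavelength
#' using the reference mean optical properties, attaches correlator noise at
#' the stated per-fiber count rates (on four co-located fibers, 10-s
#' integration by default), and reports the noise-level ratio of each
#' wavelength to the reference (longest) wavelength at the shorter
#' wavelength's half-decay lag.
#'
#' @param wavelength_nm Wavelengths (default `c(765, 785, 850, 1064)`; the
#'   last is the comparison reference).
#' @param count_rate_cps Per-fiber count rates, same order (defaults 7000,
#'   8050, 10900, 42500).
#' @param bfi Blood flow index (default 2e-8 cm^2/s).
#' @param beta Coherence factor (default 0.5).
#' @param t_int_s Integration time (default 10 s).
#' @param n_fibers Co-located fibers (default 4).
#' @param rho_cm Separation (default 3 cm).
#' @param seed Seed for the noise draw.
#' @param properties Optical-property table with `wavelength_nm`,
#'   `mua_mean`, `musp_mean` (default the bundled reference values).
#' @param tau Lag grid.
#' @return List: `curves` (long tibble: wavelength, tau_s, g2_clean,
#'   g2_noisy, sigma), `noise_ratio` (tibble of sigma ratios vs reference at
#'   each wavelength's half-decay lag).
#' @examples
#' st <- simulate_g2_study(seed = 1)
#' st$noise_ratio
#' @export
simulate_g2_study <- function(wavelength_nm = c(765, 785, 850, 1064),
                              count_rate_cps = c(7000, 8050, 10900, 42500),
                              bfi = 2e-8, beta = 0.5, t_int_s = 10,
                              n_fibers = 4, rho_cm = 3, seed = 1,
                              properties = reference_population_properties(),
                              tau = lag_grid()) {
  stopifnot(length(count_rate_cps) == length(wavelength_nm))
  per_wl <- purrr::map(seq_along(wavelength_nm), function(i) {
    wl <- wavelength_nm[i]
    j <- match(wl, properties$wavelength_nm)
    if (is.na(j)) abort("properties table lacks a needed wavelength")
    geo <- dcs_geometry(rho_cm, wl)
    clean <- simulate_g2(geo, properties$mua_mean[j], properties$musp_mean[j],
                         bfi, beta, tau)
    settings <- noise_settings(count_rate_cps[i], n_fibers = n_fibers,
                               t_int_s = t_int_s)
    settings$gamma <- resolve_gamma(clean, settings)
    sigma <- g2_noise_std(tau, settings, beta) / sqrt(n_fibers)
    noisy <- add_g2_noise(clean, settings, seed = frame_seed(seed, i))
    half_lag <- tau[which.min(abs(clean$g2 - (1 + beta / 2)))]
    list(wl = wl, clean = clean, noisy = noisy, sigma = sigma,
         half_lag = half_lag)
  })
  curves <- purrr::map_dfr(per_wl, function(p) {
    tibble::tibble(wavelength_nm = p$wl, tau_s = p$clean$tau_s,
                   g2_clean = p$clean$g2, g2_noisy = p$noisy$g2,
                   sigma = p$sigma)
  })
  ref <- per_wl[[length(per_wl)]]
  noise_ratio <- purrr::map_dfr(per_wl[-length(per_wl)], function(p) {
    i <- which.min(abs(p$clean$tau_s - p$half_lag))
    tibble::tibble(wavelength_nm = p$wl,
                   reference_nm = ref$wl,
                   half_decay_lag_s = p$half_lag,
                   sigma_wl = p$sigma[i], sigma_ref = ref$sigma[i],
                   sigma_ratio = p$sigma[i] / ref$sigma[i])
  })
  list(curves = curves, noise_ratio = noise_ratio)
}

#' Detection power study driver
#'
#' Chains the Monte Carlo transport and the statistical pipeline at the
#' preset scale: one white transport run per wavelength (reused across all
#' deep-flow levels) followed by noise synthesis, per-frame BFi fitting, and
#' segment-paired significance testing.
#'
#' @param scale `"desk"` or `"full"`.
#' @param wavelength_nm Wavelengths to include (default all three of the
#'   standard design).
#' @param seed Master seed.
#' @param ... Overrides passed to [study_design()].
#' @return A `dcsim_power_study`.
#' @export
run_deep_flow_study <- function(scale = c("desk", "full"),
                                wavelength_nm = c(765, 850, 1064),
                                seed = 1, ...) {
  preset <- study_preset(match.arg(scale))
  base <- study_design(...)
  keep <- match(wavelength_nm, base$wavelength_nm)
  if (any(is.na(keep))) abort("wavelength_nm must be a subset of the design")
  design <- study_design(wavelength_nm = base$wavelength_nm[keep],
                         count_rate_cps = base$count_rate_cps[keep],
                         musp = base$musp[keep],
                         change_pct = preset$change_pct, ...)
  run_detection_power_study(design, n_photons = preset$n_photons, seed = seed)
}
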