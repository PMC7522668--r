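#' Design of the deep-flow detection power study
#'
#' Encodes the two-layer head measurement scenario: a 1-cm superficial layer
#' (30 uM HbT, 66% SO2, water fraction 0.6, no fat, BFi 1e-8 cm^2/s) over a
#' semi-infinite cerebral layer (80 uM HbT, 62.5% SO2, water fraction 0.75,
#' no fat, BFi 6e-8 cm^2/s); homogeneous reduced scattering of 9, 8, and 6
#' cm^-1 at 765, 850, and 1064 nm; a 3-cm source-detector separation; and
#' per-fiber count rates of 7, 10.9, and 42.5 kcps on four co-located
#' fibers. Detection statistics follow the 60-frame / six-segment / 36-trial
#' protocol at alpha = 0.05.
#'
#' @param wavelength_nm Wavelengths to study.
#' @param count_rate_cps Per-fiber count rates, same length.
#' @param musp Homogeneous reduced scattering per wavelength (cm^-1).
#' @param change_pct Deep-flow increase grid in percent (default 5 to 100 by
#'   5; the full-resolution protocol uses 1 to 100 by 1).
#' @param n_frames Frames per flow level (default 60).
#' @param frame_t_s Integration time per frame (s, default 1).
#' @param segment_length Frames per segment (default 10).
#' @param alpha Significance level (default 0.05).
#' @param n_fibers Co-located fibers (default 4).
#' @param rho_cm Source-detector separation (cm).
#' @param superficial,deep One-row data frames with `hbt_uM`, `so2`,
#'   `f_water`, `f_fat`, `bfi`.
#' @param thickness_cm Superficial layer thickness (cm, default 1).
#' @param beta Coherence factor (default 0.5).
#' @param test `"welch"` (default) or `"wilcoxon"`.
#' @param table Extinction table for composition-derived absorption.
#' @return List of class `study_design`.
#' @export
study_design <- function(wavelength_nm = c(765, 850, 1064),
                         count_rate_cps = c(7000, 10900, 42500),
                         musp = c(9, 8, 6),
                         change_pct = seq(5, 100, by = 5),
                         n_frames = 60, frame_t_s = 1, segment_length = 10,
                         alpha = 0.05, n_fibers = 4, rho_cm = 3,
                         superficial = data.frame(hbt_uM = 30, so2 = 0.66,
                                                  f_water = 0.6, f_fat = 0,
                                                  bfi = 1e-8),
                         deep = data.frame(hbt_uM = 80, so2 = 0.625,
                                           f_water = 0.75, f_fat = 0,
                                           bfi = 6e-8),
                         thickness_cm = 1, beta = 0.5,
                         test = c("welch", "wilcoxon"),
                         table = extinction_table()) {
  stopifnot(length(count_rate_cps) == length(wavelength_nm),
            length(musp) == length(wavelength_nm))
  if (any(change_pct <= 0)) abort("change_pct must be positive")
  if (n_frames %% segment_length != 0) {
    abort("n_frames must be divisible by segment_length")
  }
  test <- match.arg(test)
  mua_of <- function(comp, wl) {
    tissue_absorption(tissue_composition(comp$hbt_uM, comp$so2,
                                         comp$f_water, comp$f_fat),
                      wl, table)$mua
  }
  structure(list(
    wavelength_nm = wavelength_nm, count_rate_cps = count_rate_cps,
    musp = musp, change_pct = change_pct, n_frames = n_frames,
    frame_t_s = frame_t_s, segment_length = segment_length, alpha = alpha,
    n_fibers = n_fibers, rho_cm = rho_cm, superficial = superficial,
    deep = deep, thickness_cm = thickness_cm, beta = beta, test = test,
    mua_superficial = vapply(wavelength_nm, function(wl)
      mua_of(superficial, wl), numeric(1)),
    mua_deep = vapply(wavelength_nm, function(wl) mua_of(deep, wl), numeric(1))),
    class = "study_design")
}

#' Build the study's layered medium at one wavelength
#'
#' @param design A [study_design()].
#' @param wavelength_nm One of the design's wavelengths.
#' @return A [layered_medium()].
#' @export
design_medium <- function(design, wavelength_nm) {
  i <- match(wavelength_nm, design$wavelength_nm)
  if (is.na(i)) abort("wavelength not in design")
  layered_medium(c(design$thickness_cm, Inf),
                 mua = c(design$mua_superficial[i], design$mua_deep[i]),
                 musp = rep(design$musp[i], 2),
                 bfi = c(design$superficial$bfi, design$deep$bfi),
                 wavelength_nm = wavelength_nm)
}

#' Segment two fit sequences and run all paired trials
#'
#' Splits each sequence of per-frame BFi fits into contiguous segments and
#' tests every baseline-segment x elevated-segment pairing for a significant
#' difference (Welch two-sample t-test by default, Wilcoxon rank-sum as an
#' option). With 60-frame sequences and 10-frame segments this yields the
#' 6 x 6 = 36 paired trials of the standard protocol.
#'
#' @param baseline,elevated Numeric vectors of fitted BFi values.
#' @param segment_length Frames per segment; must divide both lengths.
#' @param alpha Significance level.
#' @param test `"welch"` or `"wilcoxon"`.
#' @return Tibble with one row per trial: segment indices, `p_value`,
#'   `significant`.
#' @examples
#' segment_and_trial(rnorm(60, 6e-8, 1e-9), rnorm(60, 7e-8, 1e-9), 10)
#' @export
segment_and_trial <- function(baseline, elevated, segment_length = 10,
                              alpha = 0.05, test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  if (length(baseline) %% segment_length != 0 ||
      length(elevated) %% segment_length != 0) {
    abort("sequence length must be divisible by segment_length")
  }
  split_seg <- function(x) split(x, ceiling(seq_along(x) / segment_length))
  bs <- split_seg(baseline); es <- split_seg(elevated)
  grid <- tidyr::expand_grid(baseline_segment = seq_along(bs),
                             elevated_segment = seq_along(es))
  p_of <- function(a, b) {
    if (sd(a) == 0 && sd(b) == 0) {
      # zero-variance limit: any nonzero difference is unambiguous
      return(if (mean(a) == mean(b)) 1 else 0)
    }
    if (test == "welch") t.test(a, b)$p.value
    else wilcox.test(a, b, exact = FALSE)$p.value
  }
  grid$p_value <- purrr::map2_dbl(grid$baseline_segment, grid$elevated_segment,
                                  function(i, j) p_of(bs[[i]], es[[j]]))
  grid$significant <- grid$p_value < alpha
  grid
}

# fit BFi for every frame of a long (frame, tau_s, g2) tibble; the lag
# window is fixed across frames (derived once from the clean baseline), as
# an analyst would fix the fit range for a measurement series
fit_frames <- function(frames, geometry, mua, musp, beta, window = NULL) {
  purrr::map_dbl(split(frames, frames$frame), function(fr) {
    fit <- fit_bfi(fr, geometry, mua, musp, beta = beta, window = window)
    if (fit$converged || fit$at_boundary) fit$bfi else NA_real_
  })
}

#' Run the deep-flow detection power study
#'
#' For each wavelength: builds the two-layer clean g2 from Monte Carlo
#' photon records, then for the baseline and each elevated deep-flow level
#' synthesizes `n_frames` noisy 1-s frames with the correlation noise model,
#' fits a homogeneous semi-infinite BFi to every frame (using the design's
#' homogeneous scattering and the deep-layer absorption; the fitted value is
#' an effective index whose change proxies deep flow), splits the fits into
#' segments, and reports the fraction of baseline x elevated pairings that
#' detect a significant difference.
#'
#' Monte Carlo records are generated once per wavelength (white transport is
#' reused across flow levels) unless supplied in `records`.
#'
#' @param design A [study_design()].
#' @param records Optional named list of photon-record tibbles, names the
#'   wavelengths; otherwise generated with `n_photons` per wavelength.
#' @param n_photons Photons per transport run when generating records.
#' @param seed Master seed (drives transport and every noise realization).
#' @param tau Lag grid for the synthesized curves.
#' @return Object of class `dcsim_power_study`: tibble `results` with one
#'   row per wavelength per change level (`p_detect`, `n_trials`,
#'   `mean_bfi_baseline`, `mean_bfi_elevated`, `n_failed_fits`, `valid`)
#'   plus the design and seeds.
#' @examples
#' \donttest{
#' des <- study_design(wavelength_nm = 1064, count_rate_cps = 42500,
#'                     musp = 6, change_pct = 20)
#' ps <- run_detection_power_study(des, n_photons = 2e5, seed = 1)
#' ps$results
#' }
#' @export
run_detection_power_study <- function(design, records = NULL,
                                      n_photons = 1e7, seed = 1,
                                      tau = lag_grid()) {
  res <- purrr::imap_dfr(
    setNames(seq_along(design$wavelength_nm),
             design$wavelength_nm), function(wi, wname) {
    wl <- design$wavelength_nm[wi]
    med <- design_medium(design, wl)
    rec <- if (!is.null(records)) records[[as.character(wl)]] else NULL
    if (is.null(rec)) {
      rec <- run_photon_mc(med, n_photons, rho_cm = design$rho_cm,
                           seed = frame_seed(seed, 1000 + wi))
    }
    geometry <- dcs_geometry(design$rho_cm, wl)
    mua_fit <- design$mua_deep[wi]
    musp_fit <- design$musp[wi]
    settings <- noise_settings(design$count_rate_cps[wi],
                               n_fibers = design$n_fibers,
                               t_int_s = design$frame_t_s)

    bfi_base <- c(design$superficial$bfi, design$deep$bfi)
    clean_base <- g2_from_records(rec, bfi = bfi_base, tau = tau,
                                  beta = design$beta)
    base_fit <- fit_bfi(clean_base, geometry, mua_fit, musp_fit,
                        beta = design$beta)
    window <- fit_window(tau, geometry, mua_fit, musp_fit, base_fit$bfi,
                         design$beta)
    frames_base <- synthesize_g2_sequence(clean_base, settings,
                                          design$n_frames,
                                          design$frame_t_s,
                                          seed = frame_seed(seed, 2000 + wi))
    fits_base <- fit_frames(frames_base, geometry, mua_fit, musp_fit,
                            design$beta, window = window)

    purrr::map_dfr(seq_along(design$change_pct), function(ci) {
      chg <- design$change_pct[ci]
      bfi_elev <- c(design$superficial$bfi, design$deep$bfi * (1 + chg / 100))
      clean_elev <- g2_from_records(rec, bfi = bfi_elev, tau = tau,
                                    beta = design$beta)
      frames_elev <- synthesize_g2_sequence(
        clean_elev, settings, design$n_frames, design$frame_t_s,
        seed = frame_seed(seed, 3000 + 100 * wi + ci))
      fits_elev <- fit_frames(frames_elev, geometry, mua_fit, musp_fit,
                              design$beta, window = window)
      n_failed <- sum(is.na(fits_base)) + sum(is.na(fits_elev))
      valid <- n_failed <= 0.2 * 2 * design$n_frames
      trials <- segment_and_trial(fits_base[!is.na(fits_base)][
                                    seq_len(floor(sum(!is.na(fits_base)) /
                                      design$segment_length) *
                                      design$segment_length)],
                                  fits_elev[!is.na(fits_elev)][
                                    seq_len(floor(sum(!is.na(fits_elev)) /
                                      design$segment_length) *
                                      design$segment_length)],
                                  design$segment_length, design$alpha,
                                  design$test)
      tibble::tibble(wavelength_nm = wl, change_pct = chg,
                     p_detect = mean(trials$significant),
                     n_trials = nrow(trials),
                     mean_bfi_baseline = mean(fits_base, na.rm = TRUE),
                     mean_bfi_elevated = mean(fits_elev, na.rm = TRUE),
                     n_failed_fits = n_failed, valid = valid)
    })
  })
  structure(list(results = res, design = design, seed = seed,
                 n_photons = n_photons),
            class = "dcsim_power_study")
}

#' @export
print.dcsim_power_study <- function(x, ...) {
  cat(sprintf("Deep-flow detection power study (seed %d, %g photons/run)\n",
              x$seed, x$n_photons))
  print(x$results)
  invisible(x)
}

#' @rdname run_detection_power_study
#' @param x A `dcsim_power_study`.
#' @param ... Unused.
#' @export
tidy.dcsim_power_study <- function(x, ...) x$results
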