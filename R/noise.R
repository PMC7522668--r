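#' Correlator noise settings
#'
#' Settings for the correlation noise model: per-fiber detected count rate,
#' number of co-located detector fibers, correlator base bin width, and
#' integration time. The decay rate Gamma used inside the noise model can be
#' supplied directly or estimated from a clean curve with
#' [estimate_decay_rate()].
#'
#' @param count_rate_cps Detected count rate per fiber (photons/s, > 0).
#' @param n_fibers Number of co-located fibers averaged together (>= 1).
#' @param bin_width_s Correlator base bin width T (s, > 0; default 1e-7).
#' @param t_int_s Integration time t (s, >= T).
#' @param gamma Decay-rate estimate Gamma (1/s), or NA to estimate per curve.
#' @param gamma_source How gamma was obtained (free-text bookkeeping).
#' @return A list of validated settings.
#' @examples
#' noise_settings(42500, t_int_s = 10)
#' @export
noise_settings <- function(count_rate_cps, n_fibers = 4, bin_width_s = 1e-7,
                           t_int_s = 1, gamma = NA_real_,
                           gamma_source = if (is.na(gamma)) "fit to clean g1" else "supplied") {
  if (count_rate_cps <= 0) abort("count_rate_cps must be > 0")
  if (n_fibers < 1) abort("n_fibers must be >= 1")
  if (bin_width_s <= 0) abort("bin_width_s must be > 0")
  if (t_int_s < bin_width_s) abort("t_int_s must be >= bin_width_s")
  list(count_rate_cps = count_rate_cps, n_fibers = n_fibers,
       bin_width_s = bin_width_s, t_int_s = t_int_s, gamma = gamma,
       gamma_source = gamma_source)
}

#' Estimate an effective exponential decay rate from a clean g1
#'
#' Fits `g1 ~ exp(-Gamma tau)` by linear regression of log(g1) on tau over
#' the central decay: a two-decade window centred (in log-lag) on the 1/e
#' crossing. Used to feed the single-exponential correlation noise model.
#'
#' @param tau_s Lag grid (s).
#' @param g1 Clean field autocorrelation values.
#' @return Gamma in 1/s.
#' @export
estimate_decay_rate <- function(tau_s, g1) {
  pos <- g1 > 1e-12
  ce <- which(pos & g1 <= exp(-1))
  if (length(ce) == 0) {
    # barely decaying curve: use the full grid
    win <- pos
  } else {
    tau_e <- tau_s[ce[1]]
    win <- pos & tau_s >= tau_e / 10 & tau_s <= tau_e * 10
  }
  if (sum(win) < 3) abort("not enough decaying points to estimate Gamma")
  fit <- lm(log(g1[win]) ~ tau_s[win])
  g <- -unname(coef(fit)[2])
  if (!is.finite(g) || g <= 0) abort("estimated Gamma is not positive")
  g
}

#' Lag-dependent standard deviation of the g2 estimate
#'
#' Single-speckle estimator-variance model for a photon-counting correlator
#' (Koppel-style, as used for DCS): with bin width T, integration time t,
#' mean counts per bin `<n> = I T`, lag channel `m = tau / T`, and effective
#' single-exponential field decay rate Gamma,
#' \deqn{\sigma(\tau) = \sqrt{T/t} \left[ \beta^2 \frac{(1+e^{-2\Gamma T})(1+e^{-2\Gamma\tau}) + 2m(1-e^{-2\Gamma T})e^{-2\Gamma\tau}}{1-e^{-2\Gamma T}} + 2\langle n\rangle^{-1}\beta(1+e^{-2\Gamma\tau}) + \langle n\rangle^{-2}(1+\beta e^{-\Gamma\tau}) \right]^{1/2}}
#'
#' This is the per-fiber (single-speckle) noise; averaging F co-located
#' fibers divides it by sqrt(F) (applied in [add_g2_noise()], not here).
#'
#' @param tau_s Lag grid (s).
#' @param settings From [noise_settings()]; `gamma` must be set.
#' @param beta Coherence factor.
#' @return Per-lag standard deviation of g2.
#' @examples
#' s <- noise_settings(42500, t_int_s = 10, gamma = 2000)
#' g2_noise_std(lag_grid(16), s, beta = 0.5)
#' @export
g2_noise_std <- function(tau_s, settings, beta = 0.5) {
  gam <- settings$gamma
  if (is.na(gam) || gam <= 0) abort("settings$gamma must be a positive decay rate")
  tt <- settings$bin_width_s
  t_int <- settings$t_int_s
  nbar <- settings$count_rate_cps * tt
  m <- tau_s / tt
  e2T <- exp(-2 * gam * tt)
  e2t <- exp(-2 * gam * tau_s)
  e1t <- exp(-gam * tau_s)
  v <- beta^2 * ((1 + e2T) * (1 + e2t) + 2 * m * (1 - e2T) * e2t) / (1 - e2T) +
    2 / nbar * beta * (1 + e2t) +
    1 / nbar^2 * (1 + beta * e1t)
  sqrt(tt / t_int) * sqrt(v)
}

# resolve gamma: use the supplied one or estimate from the clean curve
resolve_gamma <- function(curve, settings) {
  if (!is.na(settings$gamma)) return(settings$gamma)
  beta <- attr(curve, "beta") %||% 0.5
  g1 <- sqrt(pmax((curve$g2 - 1) / beta, 0))
  estimate_decay_rate(curve$tau_s, g1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Add correlator noise to a clean g2 curve
#'
#' Perturbs each lag of a noise-free curve with independent zero-mean
#' Gaussian noise of standard deviation `sigma(tau) / sqrt(F)`, where sigma
#' comes from [g2_noise_std()] and F is the number of co-located fibers.
#' Noisy values may cross 1 or 1 + beta; they are not clipped.
#'
#' With `average_fibers = TRUE` the F fibers are instead synthesized as
#' explicit independent noisy curves and averaged — identical in
#' distribution, provided as a cross-check.
#'
#' @param curve Clean [g2_curve()].
#' @param settings From [noise_settings()].
#' @param seed Integer seed (reproducible); NULL leaves the RNG state alone.
#' @param average_fibers Use the explicit-averaging construction.
#' @return A noisy [g2_curve()] with the settings attached.
#' @examples
#' geo <- dcs_geometry(3, 1064)
#' clean <- simulate_g2(geo, 0.18, 6, 2e-8)
#' noisy <- add_g2_noise(clean, noise_settings(42500, t_int_s = 10), seed = 7)
#' @export
add_g2_noise <- function(curve, settings, seed = NULL, average_fibers = FALSE) {
  if (isTRUE(attr(curve, "noisy"))) abort("curve is already noisy")
  beta <- attr(curve, "beta") %||% 0.5
  settings$gamma <- resolve_gamma(curve, settings)
  sig <- g2_noise_std(curve$tau_s, settings, beta)
  if (!is.null(seed)) set.seed(seed)
  nt <- length(curve$tau_s)
  if (average_fibers) {
    eps <- rowMeans(matrix(rnorm(nt * settings$n_fibers, sd = sig),
                           nrow = nt, ncol = settings$n_fibers))
  } else {
    eps <- rnorm(nt, sd = sig / sqrt(settings$n_fibers))
  }
  out <- g2_curve(curve$tau_s, curve$g2 + eps, beta = beta,
                  count_rate_cps = settings$count_rate_cps,
                  t_int_s = settings$t_int_s, noisy = TRUE)
  attr(out, "noise_settings") <- settings
  out
}

# deterministic per-frame seed derived from a master seed
frame_seed <- function(master, frame) {
  (as.integer(master) + 99991L * as.integer(frame)) %% 2147483647L
}

#' Synthesize a sequence of noisy measurement frames
#'
#' Generates `n_frames` independent noisy realizations of a clean curve,
#' each with integration time `frame_t_s`; per-frame seeds are derived from
#' the master seed by frame index, so any frame can be regenerated alone.
#'
#' @param curve Clean [g2_curve()].
#' @param settings From [noise_settings()] (its `t_int_s` is overridden by
#'   `frame_t_s`).
#' @param n_frames Number of frames (>= 1).
#' @param frame_t_s Integration time per frame (s, default 1).
#' @param seed Master seed.
#' @return Long tibble with columns `frame`, `tau_s`, `g2`.
#' @examples
#' geo <- dcs_geometry(3, 1064)
#' clean <- simulate_g2(geo, 0.18, 6, 2e-8)
#' frames <- synthesize_g2_sequence(clean, noise_settings(42500), 5, seed = 1)
#' @export
synthesize_g2_sequence <- function(curve, settings, n_frames, frame_t_s = 1,
                                   seed = 1) {
  if (n_frames < 1) abort("n_frames must be >= 1")
  settings$t_int_s <- frame_t_s
  settings$gamma <- resolve_gamma(curve, settings)
  purrr::map_dfr(seq_len(n_frames), function(i) {
    noisy <- add_g2_noise(curve, settings, seed = frame_seed(seed, i))
    tibble::tibble(frame = i, tau_s = noisy$tau_s, g2 = noisy$g2)
  })
}
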