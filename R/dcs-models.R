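#' DCS measurement geometry
#'
#' @param rho_cm Source-detector separation (cm, > 0).
#' @param wavelength_nm Illumination wavelength (nm).
#' @param n_tissue Tissue refractive index (default 1.37).
#' @param n_external External (coupling) refractive index (default 1.0).
#' @return A list with the inputs plus `k0` (2 pi n / lambda, cm^-1).
#' @examples
#' dcs_geometry(3, 1064)
#' @export
dcs_geometry <- function(rho_cm = 3, wavelength_nm, n_tissue = 1.37,
                         n_external = 1.0) {
  if (rho_cm <= 0) abort("rho_cm must be > 0")
  if (n_tissue < 1) abort("n_tissue must be >= 1")
  list(rho_cm = rho_cm, wavelength_nm = wavelength_nm, n_tissue = n_tissue,
       n_external = n_external,
       k0 = 2 * pi * n_tissue / (wavelength_nm * 1e-7))
}

#' Effective reflection coefficient at a refractive-index mismatch
#'
#' Standard polynomial approximation in the relative index `n = n_in / n_out`
#' used for the extrapolated-boundary condition of the diffusion model.
#'
#' @param n_rel Relative refractive index (inside / outside).
#' @return Effective reflection coefficient in (0, 1).
#' @export
effective_reflection <- function(n_rel) {
  -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
}

#' Default logarithmic lag grid
#'
#' @param n Number of lags (default 128).
#' @param from,to Lag range in seconds (default 1e-7 to 1e-2).
#' @return Strictly increasing numeric vector of lags.
#' @export
lag_grid <- function(n = 128, from = 1e-7, to = 1e-2) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Semi-infinite correlation-diffusion field autocorrelation
#'
#' Normalized field autocorrelation g1(tau) for a point source on a
#' semi-infinite homogeneous medium, using the extrapolated-boundary Green's
#' function: `G1(tau) ~ exp(-K r1)/r1 - exp(-K rb)/rb` with
#' `K(tau) = sqrt(3 mua musp + 6 musp^2 k0^2 BFi tau)`. Scatterer motion is
#' Brownian with mean-square displacement `6 BFi tau` (this fixes the
#' factor-of-2 convention: the dynamic term in K^2 is
#' `6 musp^2 k0^2 BFi tau`).
#'
#' @param tau Lag times (s).
#' @param geometry From [dcs_geometry()].
#' @param mua,musp Optical properties (cm^-1); `musp` must be > 0.
#' @param bfi Blood flow index alpha*Db (cm^2/s, >= 0).
#' @return g1 values on `tau`; g1(0) = 1.
#' @examples
#' g <- dcs_geometry(3, 765)
#' g1_semi_infinite(lag_grid(16), g, mua = 0.19, musp = 9.2, bfi = 2e-8)
#' @export
g1_semi_infinite <- function(tau, geometry, mua, musp, bfi) {
  if (musp <= 0) abort("musp must be > 0")
  if (mua < 0 || bfi < 0) abort("mua and bfi must be >= 0")
  if (geometry$rho_cm * musp < 5) {
    warn("rho * musp < 5: the diffusion model is marginal this close to the source")
  }
  reff <- effective_reflection(geometry$n_tissue / geometry$n_external)
  z0 <- 1 / musp
  zb <- 2 * (1 + reff) / (3 * musp * (1 - reff))
  r1 <- sqrt(geometry$rho_cm^2 + z0^2)
  rb <- sqrt(geometry$rho_cm^2 + (z0 + 2 * zb)^2)
  kk <- sqrt(3 * mua * musp + 6 * musp^2 * geometry$k0^2 * bfi * tau)
  g1 <- (exp(-kk * r1) / r1 - exp(-kk * rb) / rb)
  k_static <- sqrt(3 * mua * musp)
  g1 / (exp(-k_static * r1) / r1 - exp(-k_static * rb) / rb)
}

#' Siegert relation
#'
#' `g2 = 1 + beta * g1^2` for ergodic speckle with coherence factor beta.
#'
#' @param g1 Field autocorrelation values, |g1| <= 1.
#' @param beta Coherence factor in (0, 1]; 0.5 for polarization-insensitive
#'   single-mode detection.
#' @return g2 values.
#' @export
siegert <- function(g1, beta = 0.5) {
  if (beta <= 0 || beta > 1) abort("beta must lie in (0, 1]")
  if (any(abs(g1) > 1 + 1e-9)) abort("|g1| must be <= 1")
  1 + beta * g1^2
}

#' Construct a g2 curve tibble
#'
#' The common container for simulated and synthetic-noise autocorrelation
#' curves: a tibble of `(tau_s, g2)` carrying beta, count rate, integration
#' time, and a noisy/clean flag as attributes.
#'
#' @param tau_s Lag grid (s), strictly increasing.
#' @param g2 Intensity autocorrelation values.
#' @param beta Coherence factor.
#' @param count_rate_cps Per-fiber detected count rate (photons/s), or NA.
#' @param t_int_s Integration time (s), or NA.
#' @param noisy Logical flag.
#' @return Tibble of class `g2_curve`.
#' @export
g2_curve <- function(tau_s, g2, beta = 0.5, count_rate_cps = NA_real_,
                     t_int_s = NA_real_, noisy = FALSE) {
  if (is.unsorted(tau_s, strictly = TRUE)) abort("tau_s must be strictly increasing")
  out <- tibble::tibble(tau_s = tau_s, g2 = g2)
  class(out) <- c("g2_curve", class(out))
  attr(out, "beta") <- beta
  attr(out, "count_rate_cps") <- count_rate_cps
  attr(out, "t_int_s") <- t_int_s
  attr(out, "noisy") <- noisy
  out
}

#' Simulate a noise-free semi-infinite g2 curve
#'
#' @inheritParams g1_semi_infinite
#' @param beta Coherence factor.
#' @param tau Lag grid (default [lag_grid()]).
#' @return A [g2_curve()] tibble.
#' @examples
#' simulate_g2(dcs_geometry(3, 1064), mua = 0.18, musp = 6, bfi = 2e-8)
#' @export
simulate_g2 <- function(geometry, mua, musp, bfi, beta = 0.5,
                        tau = lag_grid()) {
  g1 <- g1_semi_infinite(tau, geometry, mua, musp, bfi)
  g2_curve(tau, siegert(g1, beta), beta = beta)
}

# default fit window: lags where the model at bfi0 lies within the central
# band of the decay, widened one decade on each side
fit_window <- function(tau, geometry, mua, musp, bfi0, beta) {
  g2m <- siegert(g1_semi_infinite(tau, geometry, mua, musp, bfi0), beta)
  core <- g2m >= 1 + 0.05 * beta & g2m <= 1 + 0.95 * beta
  if (!any(core)) return(rep(TRUE, length(tau)))
  lo <- min(tau[core]) / 10
  hi <- max(tau[core]) * 10
  tau >= lo & tau <= hi
}

# 1/e-crossing heuristic for the initial BFi; the curve is smoothed with a
# short running mean first so that a single noisy lag cannot fake a crossing
initial_bfi <- function(tau, g2, geometry, mua, musp, beta) {
  y <- (g2 - 1) / beta
  k <- min(7L, max(1L, length(y) %/% 8L))
  if (k > 1) {
    ys <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
    y <- ifelse(is.na(ys), y, ys)
  }
  target <- exp(-2)  # g1 = 1/e
  below <- which(y <= target)
  if (length(below) == 0 || below[1] == 1) return(NA_real_)
  tau_e <- tau[below[1]]
  f <- function(lb) g1_semi_infinite(tau_e, geometry, mua, musp, 10^lb) - exp(-1)
  out <- tryCatch(uniroot(f, c(-14, -2), tol = 1e-4)$root, error = function(e) NA_real_)
  if (is.na(out)) NA_real_ else 10^out
}

#' Fit a blood flow index to a g2 curve
#'
#' Least-squares fit of the semi-infinite correlation-diffusion model (via
#' the Siegert relation) to a measured or synthesized g2 curve. BFi is
#' searched in log space with a deterministic bounded optimizer, initialized
#' from the 1/e-crossing of the data. beta is fixed (default 0.5) unless
#' `fit_beta = TRUE`, in which case (log10 BFi, beta) are fitted jointly.
#'
#' The default fit window keeps lags where the model at the initial BFi lies
#' within `[1 + 0.05 beta, 1 + 0.95 beta]`, extended one decade on each side.
#'
#' @param curve A [g2_curve()] or data frame with `tau_s` and `g2`.
#' @param geometry From [dcs_geometry()].
#' @param mua,musp Optical properties assumed in the fit (cm^-1).
#' @param beta Coherence factor (fixed value, or starting value if fitted).
#' @param fit_beta Fit beta jointly with BFi?
#' @param weights Optional per-lag weights (e.g. inverse noise variance);
#'   default uniform over the fit window.
#' @param window Optional logical vector selecting lags; default as above.
#' @return Object of class `bfi_fit`: list with `bfi`, `beta`, `converged`,
#'   `degenerate`, `objective`, the fitted curve, and the data. Supports
#'   [tidy()], [glance()], [autoplot()].
#' @examples
#' geo <- dcs_geometry(3, 850)
#' cur <- simulate_g2(geo, 0.2, 8, 3e-8)
#' fit <- fit_bfi(cur, geo, 0.2, 8)
#' glance(fit)
#' @export
fit_bfi <- function(curve, geometry, mua, musp, beta = 0.5, fit_beta = FALSE,
                    weights = NULL, window = NULL) {
  tau <- curve$tau_s
  g2 <- curve$g2
  if (length(tau) < 16) abort("need at least 16 lags to fit")
  decay <- max(g2) - min(g2)
  degenerate <- decay < 0.02 * beta
  bfi0 <- if (degenerate) NA_real_ else initial_bfi(tau, g2, geometry, mua, musp, beta)
  if (is.na(bfi0)) bfi0 <- 1e-8
  if (is.null(window)) window <- fit_window(tau, geometry, mua, musp, bfi0, beta)
  if (is.null(weights)) weights <- rep(1, length(tau))
  w <- weights[window]; tw <- tau[window]; yw <- g2[window]

  obj <- function(lb, bet) {
    g1 <- g1_semi_infinite(tw, geometry, mua, musp, 10^lb)
    sum(w * (1 + bet * g1^2 - yw)^2)
  }
  lb_lo <- log10(bfi0) - 3; lb_hi <- log10(bfi0) + 3
  if (fit_beta) {
    fit <- nlminb(c(log10(bfi0), beta),
                  function(p) obj(p[1], p[2]),
                  lower = c(lb_lo, 1e-3), upper = c(lb_hi, 1))
    lb_hat <- fit$par[1]; beta_hat <- fit$par[2]; objective <- fit$objective
    conv_code <- fit$convergence == 0
  } else {
    fit <- optimize(function(lb) obj(lb, beta), c(lb_lo, lb_hi), tol = 1e-7)
    lb_hat <- fit$minimum; beta_hat <- beta; objective <- fit$objective
    conv_code <- TRUE
  }
  at_boundary <- (lb_hat - lb_lo) < 1e-3 || (lb_hi - lb_hat) < 1e-3
  bfi_hat <- 10^lb_hat
  g1_hat <- g1_semi_infinite(tau, geometry, mua, musp, bfi_hat)
  structure(list(
    bfi = bfi_hat, beta = beta_hat,
    converged = conv_code && !at_boundary && !degenerate,
    degenerate = degenerate, at_boundary = at_boundary,
    objective = objective, fit_beta = fit_beta,
    geometry = geometry, mua = mua, musp = musp,
    data = tibble::tibble(tau_s = tau, g2 = g2, fitted = 1 + beta_hat * g1_hat^2,
                          in_window = window)),
    class = "bfi_fit")
}

#' @export
print.bfi_fit <- function(x, ...) {
  cat(sprintf("BFi fit: %.3e cm^2/s (beta %s %.3f)%s\n", x$bfi,
              if (x$fit_beta) "fitted" else "fixed", x$beta,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  invisible(x)
}

#' @rdname fit_bfi
#' @param x A `bfi_fit` object.
#' @param ... Unused.
#' @export
tidy.bfi_fit <- function(x, ...) {
  out <- tibble::tibble(term = "bfi", estimate = x$bfi)
  if (x$fit_beta) {
    out <- dplyr::bind_rows(out, tibble::tibble(term = "beta", estimate = x$beta))
  }
  out
}

#' @rdname fit_bfi
#' @export
glance.bfi_fit <- function(x, ...) {
  tibble::tibble(bfi = x$bfi, beta = x$beta, objective = x$objective,
                 converged = x$converged, degenerate = x$degenerate,
                 n_lags = sum(x$data$in_window))
}
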