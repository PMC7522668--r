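#' Define a layered slab medium
#'
#' Ordered layers from the surface down; the last layer is semi-infinite
#' (its thickness may be `Inf`; transport truncates it at `depth_cap_cm`).
#' The two-layer head model used throughout the deep-flow study is a 1-cm
#' superficial (scalp/skull) layer over a semi-infinite deep (cerebral)
#' layer.
#'
#' @param thickness_cm Layer thicknesses (cm, > 0; last may be Inf).
#' @param mua Per-layer absorption (cm^-1).
#' @param musp Per-layer reduced scattering (cm^-1, > 0).
#' @param bfi Per-layer blood flow index (cm^2/s, >= 0).
#' @param n_tissue Refractive index (global, default 1.37).
#' @param wavelength_nm Illumination wavelength (nm).
#' @param depth_cap_cm Truncation depth of the last layer (default 30).
#' @return Tibble of class `layered_medium`, one row per layer, with
#'   geometry attributes.
#' @examples
#' layered_medium(c(1, Inf), mua = c(0.1, 0.2), musp = c(6, 6),
#'                bfi = c(1e-8, 6e-8), wavelength_nm = 1064)
#' @export
layered_medium <- function(thickness_cm, mua, musp, bfi, n_tissue = 1.37,
                           wavelength_nm, depth_cap_cm = 30) {
  out <- tibble::tibble(layer = seq_along(thickness_cm),
                        thickness_cm = thickness_cm, mua = mua,
                        musp = musp, bfi = bfi)
  if (any(out$thickness_cm <= 0)) abort("layer thicknesses must be > 0")
  if (any(!is.finite(out$thickness_cm[-nrow(out)]))) {
    abort("only the last layer may be semi-infinite")
  }
  if (any(out$mua < 0) || any(out$bfi < 0)) abort("mua and bfi must be >= 0")
  if (any(out$musp <= 0)) abort("every layer must scatter (musp > 0)")
  class(out) <- c("layered_medium", class(out))
  attr(out, "n_tissue") <- n_tissue
  attr(out, "wavelength_nm") <- wavelength_nm
  attr(out, "depth_cap_cm") <- depth_cap_cm
  out
}

#' Run the layered-slab white Monte Carlo
#'
#' Propagates photons without absorption (white Monte Carlo) through the
#' layered medium and records, for every photon exiting the top surface
#' inside the detector annulus, its per-layer pathlengths `L_k`, per-layer
#' momentum-transfer sums `Y_k` (sum of 1 - cos(theta) over scattering
#' events in the layer), exit radius, exit time, and scattering count.
#' Absorption and layer dynamics are applied afterwards by
#' [g1_from_records()] / [reweight_records()], so one transport run serves
#' any absorption values and any per-layer BFi at matching scattering.
#'
#' By default scattering is isotropic at the reduced scattering coefficient
#' (similarity relation), which is accurate in the diffusive regime and
#' fast; `phase = "hg"` runs Henyey-Greenstein at `mus = musp / (1 - g)` as
#' a convergence check. Momentum-transfer tallies are comparable across the
#' two because the expected (1 - cos) per unit reduced pathlength matches.
#'
#' @param medium A [layered_medium()].
#' @param n_photons Photons to launch (>= 1).
#' @param rho_cm Detector annulus center radius (cm).
#' @param half_width_cm Annulus half-width (cm, default 0.1).
#' @param seed Integer seed (deterministic records).
#' @param phase `"isotropic"` (default) or `"hg"`.
#' @param g Henyey-Greenstein anisotropy (used only for `phase = "hg"`).
#' @param path_cap_cm Total-pathlength termination cap (default 100).
#' @return Tibble of photon records (`L1..Lk`, `Y1..Yk`, `exit_r_cm`,
#'   `exit_t_s`, `n_scatter`) with the run metadata in attributes.
#' @examples
#' med <- layered_medium(Inf, mua = 0.18, musp = 6, bfi = 2e-8,
#'                       wavelength_nm = 1064)
#' rec <- run_photon_mc(med, 2e4, seed = 1)
#' @export
run_photon_mc <- function(medium, n_photons, rho_cm = 3, half_width_cm = 0.1,
                          seed = 1, phase = c("isotropic", "hg"), g = 0.9,
                          path_cap_cm = 100) {
  phase <- match.arg(phase)
  if (n_photons < 1) abort("n_photons must be >= 1")
  if (rho_cm - half_width_cm <= 0) abort("annulus must exclude the source point")
  K <- nrow(medium)
  th <- medium$thickness_cm
  depth_cap <- attr(medium, "depth_cap_cm")
  th[K] <- min(th[K], depth_cap)
  if (!is.finite(th[K])) th[K] <- depth_cap
  z_bound <- c(0, cumsum(th))
  mus <- if (phase == "hg") medium$musp / (1 - g) else medium$musp
  n_rel <- attr(medium, "n_tissue")  # external index 1.0

  set.seed(seed)
  m <- mc_layered_cpp(mus, z_bound, n_rel, n_photons,
                      rho_cm - half_width_cm, rho_cm + half_width_cm,
                      path_cap_cm, if (phase == "hg") g else 0)
  cn <- c(paste0("L", seq_len(K)), paste0("Y", seq_len(K)),
          "exit_r_cm", "exit_t_s", "n_scatter")
  colnames(m) <- cn
  out <- tibble::as_tibble(m)
  out$exit_t_s <- out$exit_t_s * n_rel / .c_light_cm
  class(out) <- c("photon_records", class(out))
  attr(out, "medium") <- medium
  attr(out, "phase") <- phase
  attr(out, "g") <- if (phase == "hg") g else 0
  attr(out, "seed") <- seed
  attr(out, "n_photons") <- n_photons
  attr(out, "rho_cm") <- rho_cm
  attr(out, "half_width_cm") <- half_width_cm
  out
}

#' Recompute absorption weights for white-Monte-Carlo records
#'
#' `w_i = exp(-sum_l mua_l L_il)`: the analytic absorption weight of each
#' recorded photon for a new set of per-layer absorption coefficients. The
#' records must come from a transport run with matching scattering (white
#' Monte Carlo is reusable across absorption, not across scattering).
#'
#' @param records From [run_photon_mc()].
#' @param mua Per-layer absorption coefficients (cm^-1).
#' @param musp Per-layer reduced scattering the caller believes the records
#'   were generated with; checked against the record metadata (NULL skips
#'   the check).
#' @return Numeric weight vector, one per record.
#' @export
reweight_records <- function(records, mua, musp = NULL) {
  med <- attr(records, "medium")
  K <- nrow(med)
  if (length(mua) != K) abort("mua must have one entry per layer")
  if (!is.null(musp) && !isTRUE(all.equal(musp, med$musp))) {
    abort("scattering mismatch: records were generated with different musp")
  }
  Lm <- as.matrix(records[paste0("L", seq_len(K))])
  exp(-drop(Lm %*% mua))
}

#' Field autocorrelation from Monte Carlo photon records
#'
#' Assembles `g1(tau)` for arbitrary per-layer Brownian flow indices from
#' white-Monte-Carlo records:
#' `g1(tau) = sum_i w_i exp(-2 k0^2 tau sum_l BFi_l Y_il) / sum_i w_i`
#' with absorption weights `w_i = exp(-sum_l mua_l L_il)` and
#' `k0 = 2 pi n / lambda`.
#'
#' @param records From [run_photon_mc()].
#' @param bfi Per-layer blood flow indices (cm^2/s); default the medium's.
#' @param mua Per-layer absorption (cm^-1); default the medium's.
#' @param tau Lag grid (s).
#' @return Numeric g1 values on `tau` (g1(0) = 1, nonincreasing).
#' @examples
#' med <- layered_medium(Inf, 0.18, 6, 2e-8, wavelength_nm = 1064)
#' rec <- run_photon_mc(med, 5e4, seed = 1)
#' g1 <- g1_from_records(rec, tau = lag_grid(32))
#' @export
g1_from_records <- function(records, bfi = NULL, mua = NULL,
                            tau = lag_grid()) {
  if (nrow(records) == 0) abort("no photon records")
  med <- attr(records, "medium")
  K <- nrow(med)
  bfi <- bfi %||% med$bfi
  mua <- mua %||% med$mua
  if (length(bfi) != K) abort("bfi must have one entry per layer")
  w <- reweight_records(records, mua)
  Ym <- as.matrix(records[paste0("Y", seq_len(K))])
  s <- drop(Ym %*% bfi)
  k0 <- 2 * pi * attr(med, "n_tissue") / (attr(med, "wavelength_nm") * 1e-7)
  num <- vapply(tau, function(tt) sum(w * exp(-2 * k0^2 * tt * s)), numeric(1))
  num / sum(w)
}

#' g2 curve from Monte Carlo records
#'
#' Convenience: [g1_from_records()] followed by the Siegert relation.
#'
#' @inheritParams g1_from_records
#' @param beta Coherence factor.
#' @return A [g2_curve()].
#' @export
g2_from_records <- function(records, bfi = NULL, mua = NULL, beta = 0.5,
                            tau = lag_grid()) {
  g2_curve(tau, siegert(g1_from_records(records, bfi, mua, tau), beta),
           beta = beta)
}
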