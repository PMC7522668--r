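# shared fixtures, built once per test run

ref_tissue <- data.frame(hbt_uM = 80, so2 = 0.625, f_water = 0.75,
                         f_fat = 0.2, a = 20, b = 1.5)

# homogeneous 1064-nm medium with reference mean optical properties
homog_1064 <- function(bfi = 2e-8) {
  layered_medium(Inf, mua = 0.18, musp = 6, bfi = bfi, wavelength_nm = 1064)
}

# memoised Monte Carlo record sets shared across tests
.mc_cache <- new.env(parent = emptyenv())

cached_records <- function(key, build) {
  if (is.null(.mc_cache[[key]])) .mc_cache[[key]] <- build()
  .mc_cache[[key]]
}

records_homog_1064 <- function() {
  cached_records("h1064", function() {
    run_photon_mc(homog_1064(), 1e6, rho_cm = 3, seed = 42)
  })
}

# independent transcription of the semi-infinite correlation-diffusion model
# (kept separate from the package implementation on purpose)
oracle_g1 <- function(tau, mua, musp, rho, bfi, wavelength_nm, n = 1.37) {
  k0 <- 2 * pi * n / (wavelength_nm * 1e-7)
  reff <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  z0 <- 1 / musp
  zb <- 2 * (1 + reff) / (3 * musp * (1 - reff))
  r1 <- sqrt(rho^2 + z0^2)
  rb <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  G <- function(tt) {
    K <- sqrt(3 * mua * musp + 6 * musp^2 * k0^2 * bfi * tt)
    exp(-K * r1) / r1 - exp(-K * rb) / rb
  }
  G(tau) / G(0)
}

# brute-force photon-stream correlator: complex Gaussian single-mode field
# with g1 = exp(-gamma tau) (stationary AR(1) quadratures), Poisson photon
# thinning at nbar counts per bin, symmetric-normalized multi-lag estimator.
# Returns the empirical sd of g2-hat across realizations at lags m*T.
photon_stream_sd <- function(gamma, bin_T, n_bins, nbar, lags_m,
                             n_realizations, seed = 31) {
  set.seed(seed)
  burn <- 5000
  rho <- exp(-gamma * bin_T)
  g2hat <- matrix(NA_real_, n_realizations, length(lags_m))
  for (r in seq_len(n_realizations)) {
    E <- matrix(rnorm(2 * (n_bins + burn)), n_bins + burn, 2)
    E <- apply(E, 2, function(x)
      as.numeric(stats::filter(x * sqrt(1 - rho^2), rho, method = "recursive")))
    E <- E[(burn + 1):(burn + n_bins), ]
    n <- rpois(n_bins, nbar * rowSums(E^2) / 2)
    for (k in seq_along(lags_m)) {
      m <- lags_m[k]
      a <- n[1:(n_bins - m)]; b <- n[(m + 1):n_bins]
      g2hat[r, k] <- mean(a * b) / (mean(a) * mean(b))
    }
  }
  apply(g2hat, 2, sd)
}
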