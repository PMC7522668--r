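test_that("semi-infinite g1 normalization, static limit, and decay shape", {
  geo <- dcs_geometry(3, 765)
  tau <- lag_grid(64)
  expect_equal(g1_semi_infinite(0, geo, 0.19, 9.2, 2e-8), 1)
  expect_equal(g1_semi_infinite(tau, geo, 0.19, 9.2, 0), rep(1, 64))
  g1 <- g1_semi_infinite(tau, geo, 0.19, 9.2, 2e-8)
  expect_true(all(diff(g1) < 0))
  expect_true(all(g1 >= 0))
  expect_error(g1_semi_infinite(tau, geo, 0.19, 0, 2e-8), "musp")
  expect_warning(g1_semi_infinite(tau, dcs_geometry(0.3, 765), 0.19, 9.2, 2e-8),
                 "diffusion")
})

test_that("1/e decay lag matches the independently evaluated Green's function", {
  geo <- dcs_geometry(3, 765)
  # frozen from a high-precision independent evaluation of the
  # extrapolated-boundary quotient (765-nm mean optics, BFi = 2e-8)
  tau_e_expected <- 1.44363812e-05
  f <- function(lt) g1_semi_infinite(10^lt, geo, 0.19, 9.2, 2e-8) - exp(-1)
  tau_e <- 10^uniroot(f, c(-8, -2), tol = 1e-12)$root
  expect_equal(tau_e, tau_e_expected, tolerance = 1e-6)
  # and against the helper transcription across the whole decay
  tau <- lag_grid(32)
  expect_equal(g1_semi_infinite(tau, geo, 0.19, 9.2, 2e-8),
               oracle_g1(tau, 0.19, 9.2, 3, 2e-8, 765), tolerance = 1e-12)
})

test_that("g1 depends on BFi and tau only through their product", {
  geo <- dcs_geometry(3, 850)
  tau <- lag_grid(32, 1e-6, 1e-3)
  for (cc in c(3, 10)) {
    expect_equal(g1_semi_infinite(tau, geo, 0.2, 8, 2e-8),
                 g1_semi_infinite(tau / cc, geo, 0.2, 8, cc * 2e-8),
                 tolerance = 1e-12)
  }
})

test_that("Siegert relation and its validation", {
  expect_equal(siegert(1, 0.5), 1.5)
  expect_equal(siegert(0, 0.37), 1)
  expect_equal(siegert(0.5, 0.5), 1.125)
  expect_error(siegert(0.5, 0), "beta")
  expect_error(siegert(0.5, 1.2), "beta")
  expect_error(siegert(1.2, 0.5), "g1")
})

test_that("the 1064-nm g2 decays later than the 765-nm g2 at equal BFi", {
  tau <- lag_grid(64)
  g765 <- simulate_g2(dcs_geometry(3, 765), 0.19, 9.2, 2e-8, tau = tau)
  g1064 <- simulate_g2(dcs_geometry(3, 1064), 0.18, 6.0, 2e-8, tau = tau)
  decay <- g765$g2 < 1.49 & g765$g2 > 1.01
  expect_true(all(g1064$g2[decay] >= g765$g2[decay]))
})

test_that("noise-free fits recover the generating BFi and beta", {
  geo <- dcs_geometry(3, 850)
  for (bfi in c(5e-9, 2e-8, 1e-7)) {
    cur <- simulate_g2(geo, 0.2, 8, bfi)
    fit <- fit_bfi(cur, geo, 0.2, 8)
    expect_true(fit$converged)
    expect_equal(fit$bfi, bfi, tolerance = 1e-3)
  }
  cur <- simulate_g2(geo, 0.2, 8, 2e-8, beta = 0.43)
  fit <- fit_bfi(cur, geo, 0.2, 8, beta = 0.5, fit_beta = TRUE)
  expect_equal(fit$bfi, 2e-8, tolerance = 1e-3)
  expect_equal(fit$beta, 0.43, tolerance = 1e-3)
})

test_that("fitted BFi is invariant to rescaling g2 - 1 when beta is fitted", {
  geo <- dcs_geometry(3, 850)
  cur <- simulate_g2(geo, 0.2, 8, 2e-8)
  scaled <- g2_curve(cur$tau_s, 1 + 0.6 * (cur$g2 - 1), beta = 0.5)
  f1 <- fit_bfi(cur, geo, 0.2, 8, fit_beta = TRUE)
  f2 <- fit_bfi(scaled, geo, 0.2, 8, fit_beta = TRUE)
  expect_equal(f2$bfi, f1$bfi, tolerance = 1e-3)
  expect_equal(f2$beta, 0.6 * f1$beta, tolerance = 1e-3)
})

test_that("flat curves are flagged degenerate instead of fitted silently", {
  geo <- dcs_geometry(3, 850)
  flat <- g2_curve(lag_grid(32), rep(1.5, 32))
  fit <- fit_bfi(flat, geo, 0.2, 8)
  expect_true(fit$degenerate)
  expect_false(fit$converged)
  expect_error(fit_bfi(g2_curve(lag_grid(8), rep(1.2, 8)), geo, 0.2, 8),
               "16 lags")
})

test_that("fits over noisy 1-s frames at the 1064-nm count rate are unbiased", {
  geo <- dcs_geometry(3, 1064)
  bfi <- 2e-8
  clean <- simulate_g2(geo, 0.18, 6, bfi)
  frames <- synthesize_g2_sequence(clean, noise_settings(42500), 60,
                                   frame_t_s = 1, seed = 5)
  fits <- vapply(split(frames, frames$frame), function(fr)
    fit_bfi(fr, geo, 0.18, 6)$bfi, numeric(1))
  se <- sd(fits) / sqrt(length(fits))
  expect_lt(abs(mean(fits) - bfi), 1 * se + 1e-12)
})
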