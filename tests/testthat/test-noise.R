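test_that("noise sd scales as 1/sqrt(integration time) and shrinks with count rate", {
  tau <- lag_grid(32)
  s10 <- noise_settings(7000, t_int_s = 10, gamma = 2e4)
  s40 <- noise_settings(7000, t_int_s = 40, gamma = 2e4)
  expect_equal(g2_noise_std(tau, s10) / g2_noise_std(tau, s40),
               rep(2, 32), tolerance = 1e-12)
  # high-intensity limit leaves only the beta^2 (speckle) term
  s_inf <- noise_settings(1e15, t_int_s = 10, gamma = 2e4, bin_width_s = 1e-7)
  beta <- 0.5
  tt <- 1e-7; gam <- 2e4
  e2T <- exp(-2 * gam * tt); e2t <- exp(-2 * gam * tau)
  speckle_only <- sqrt(tt / 10) *
    sqrt(beta^2 * ((1 + e2T) * (1 + e2t) + 2 * (tau / tt) * (1 - e2T) * e2t) /
           (1 - e2T))
  expect_equal(g2_noise_std(tau, s_inf, beta), speckle_only, tolerance = 1e-6)
  # monotone in count rate at fixed everything else
  sds <- vapply(c(5e3, 2e4, 1e5, 1e6), function(cr)
    g2_noise_std(1e-5, noise_settings(cr, t_int_s = 10, gamma = 2e4)),
    numeric(1))
  expect_true(all(diff(sds) < 0))
  expect_error(g2_noise_std(tau, noise_settings(7000, t_int_s = 10)), "gamma")
})

test_that("noise model sd matches a brute-force photon-stream correlator", {
  gamma <- 5000; bin_T <- 1e-6; n_bins <- 1e5; nbar <- 0.2
  lags_m <- c(20, 50, 100, 200)  # decay region: gamma*tau in [0.02, 1]
  emp <- photon_stream_sd(gamma, bin_T, n_bins, nbar, lags_m,
                          n_realizations = 200, seed = 31)
  s <- noise_settings(nbar / bin_T, n_fibers = 1, bin_width_s = bin_T,
                      t_int_s = n_bins * bin_T, gamma = gamma)
  model <- g2_noise_std(lags_m * bin_T, s, beta = 1)
  expect_true(all(abs(emp / model - 1) < 0.2))
})

test_that("noisy synthesis is seeded, centered, and scaled by the fiber count", {
  geo <- dcs_geometry(3, 1064)
  clean <- simulate_g2(geo, 0.18, 6, 2e-8, tau = lag_grid(16))
  s <- noise_settings(42500, t_int_s = 1)
  a <- add_g2_noise(clean, s, seed = 123)
  b <- add_g2_noise(clean, s, seed = 123)
  expect_identical(a$g2, b$g2)
  expect_error(add_g2_noise(a, s), "already noisy")
  # ensemble std at each lag approaches sigma / sqrt(F)
  s$gamma <- dcsim:::resolve_gamma(clean, s)
  n_rep <- 10000
  eps <- vapply(seq_len(n_rep), function(i)
    add_g2_noise(clean, s, seed = i)$g2 - clean$g2, numeric(16))
  sig <- g2_noise_std(clean$tau_s, s) / sqrt(s$n_fibers)
  expect_true(all(abs(apply(eps, 1, sd) / sig - 1) < 0.03))
  # explicit fiber averaging agrees in sd within Monte Carlo error
  eps4 <- vapply(seq_len(2000), function(i)
    add_g2_noise(clean, s, seed = i, average_fibers = TRUE)$g2 - clean$g2,
    numeric(16))
  expect_true(all(abs(apply(eps4, 1, sd) / sig - 1) < 0.1))
})

test_that("frame sequences are independent and average like longer integrations", {
  geo <- dcs_geometry(3, 1064)
  tau <- lag_grid(8, 1e-6, 1e-3)
  clean <- simulate_g2(geo, 0.18, 6, 2e-8, tau = tau)
  s <- noise_settings(42500, t_int_s = 1)
  frames <- synthesize_g2_sequence(clean, s, n_frames = 60, seed = 4)
  expect_equal(dplyr::n_distinct(frames$frame), 60)
  # single-frame sequence reduces to one synthesized measurement
  one <- synthesize_g2_sequence(clean, s, n_frames = 1, seed = 4)
  direct <- add_g2_noise(clean, s, seed = dcsim:::frame_seed(4, 1))
  expect_equal(one$g2, direct$g2)
  # noise at one lag is uncorrelated across consecutive frames
  wide <- matrix(frames$g2, nrow = 8)
  eps1 <- wide[4, ] - clean$g2[4]
  r <- cor(eps1[-60], eps1[-1])
  expect_lt(abs(r), 3 / sqrt(59))
  # averaging ten 1-s frames ~ one 10-s frame in noise level
  trials <- 1000
  avg10 <- vapply(seq_len(trials), function(i) {
    fr <- synthesize_g2_sequence(clean, s, 10, seed = 10000 + i)
    mean(matrix(fr$g2, nrow = 8)[4, ])
  }, numeric(1))
  s10 <- noise_settings(42500, t_int_s = 10)
  one10 <- vapply(seq_len(trials), function(i)
    add_g2_noise(clean, s10, seed = 50000 + i)$g2[4], numeric(1))
  expect_equal(sd(avg10) / sd(one10), 1, tolerance = 0.1)
})

test_that("per-lag noise in the decay region is far smaller at 1064 nm", {
  st <- simulate_g2_study(seed = 1)
  r765 <- st$noise_ratio[st$noise_ratio$wavelength_nm == 765, ]
  expect_gt(r765$sigma_ratio, 1.5)
  expect_gt(r765$sigma_ratio, 2)  # quantitatively smaller, not marginal
})
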