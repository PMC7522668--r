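test_that("bundled extinction table is well-formed and covers the key wavelengths", {
  tab <- extinction_table()
  expect_true(all(diff(tab$wavelength_nm) > 0))
  expect_true(all(as.matrix(tab[-1]) >= 0))
  expect_true(min(tab$wavelength_nm) <= 765 && max(tab$wavelength_nm) >= 1064)
  expect_error(extinction_at(tab, 1500), "outside")
  ext <- extinction_at(tab, c(765, 785, 850, 1064))
  expect_equal(nrow(ext), 4)
})

test_that("reference brain composition reproduces the canonical absorption totals", {
  comp <- tissue_composition(80, 0.625, 0.75, 0.20)
  mua <- tissue_absorption(comp, c(765, 785, 850, 1064))$mua
  expect_equal(mua, c(0.19, 0.17, 0.20, 0.18), tolerance = 0.005 / 0.19)
  # empty medium absorbs nothing
  empty <- tissue_composition(0, 0.5, 0, 0)
  expect_equal(tissue_absorption(empty, c(700, 1100))$mua, c(0, 0))
  expect_error(tissue_composition(-1, 0.5), "hbt")
  expect_error(tissue_composition(80, 1.5), "so2")
})

test_that("scattering power law evaluates and validates", {
  expect_equal(reduced_scattering(20, 1.5, 500), 20)
  expect_equal(reduced_scattering(20, 1.5, 1064), 20 * (1064 / 500)^(-1.5))
  expect_equal(round(reduced_scattering(20, 1.5, 1064), 2), 6.44)
  expect_equal(reduced_scattering(20, 0, 2000), 20)
  expect_error(reduced_scattering(20, 1.5, -5), "wavelength")
  expect_error(reduced_scattering(-1, 1.5, 800), "scale")
})

test_that("effective attenuation closed form and edge cases", {
  expect_equal(effective_attenuation(0.19, 9.2), sqrt(3 * 0.19 * 9.39))
  expect_equal(round(effective_attenuation(0.19, 9.2), 2), 2.31)
  expect_equal(effective_attenuation(0, 12), 0)
  expect_equal(effective_attenuation(0.3, 0), sqrt(3) * 0.3)
  expect_error(effective_attenuation(-0.1, 5), ">= 0")
})

test_that("mueff rises with hemoglobin at 765 nm and with water at 1064 nm", {
  hbt_grid <- seq(40, 120, by = 20)
  t765 <- data.frame(hbt_uM = hbt_grid, so2 = 0.625, f_water = 0.75,
                     f_fat = 0.2, a = 20, b = 1.5)
  m765 <- tissue_optical_properties(t765, 765)$mueff
  expect_true(all(diff(m765) > 0))
  w_grid <- seq(0.55, 0.95, by = 0.1)
  t1064 <- data.frame(hbt_uM = 80, so2 = 0.625, f_water = w_grid,
                      f_fat = 0.2, a = 20, b = 1.5)
  m1064 <- tissue_optical_properties(t1064, 1064)$mueff
  expect_true(all(diff(m1064) > 0))
})

test_that("population sampling converges to analytic uniform-expectation means", {
  pop <- sample_tissue_population(n = 10000, seed = 11)
  # E[a (lambda/500)^-b] for independent uniforms a~U(8,25), b~U(0.5,2.4)
  musp_mean_analytic <- function(wl) {
    x <- wl / 500
    16.5 * (x^(-0.5) - x^(-2.4)) / (1.9 * log(x))
  }
  for (wl in c(765, 1064)) {
    row <- pop$summary[pop$summary$wavelength_nm == wl, ]
    se <- row$musp_sd / sqrt(pop$n)
    expect_lt(abs(row$musp_mean - musp_mean_analytic(wl)), 3 * se)
  }
})

test_that("per-sample mueff equals the closed form of its own mua and musp", {
  pop <- sample_tissue_population(n = 500, seed = 3, keep_samples = TRUE)
  for (wl in names(pop$properties)) {
    p <- pop$properties[[wl]]
    expect_equal(p$mueff, sqrt(3 * p$mua * (p$mua + p$musp)), tolerance = 1e-12)
  }
})

test_that("population summaries are seed-reproducible and degenerate ranges collapse", {
  a <- sample_tissue_population(n = 3000, seed = 99)
  b <- sample_tissue_population(n = 3000, seed = 99)
  expect_identical(a$summary, b$summary)
  expect_identical(a$pairwise, b$pairwise)
  deg <- sampling_ranges(hbt_uM = c(80, 80), so2 = c(0.625, 0.625),
                         f_water = c(0.75, 0.75), f_fat = c(0.2, 0.2),
                         a = c(20, 20), b = c(1.5, 1.5))
  pop <- sample_tissue_population(deg, n = 50, seed = 1)
  expect_true(all(abs(c(pop$summary$mua_sd, pop$summary$musp_sd,
                        pop$summary$mueff_sd)) < 1e-14))
  expect_error(sample_tissue_population(n = 0), "n")
})
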