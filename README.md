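# dcsim

Simulation toolkit for continuous-wave diffuse correlation spectroscopy
(DCS) across near-infrared wavelengths.

DCS measures deep-tissue blood flow by shining coherent light into tissue
and watching the speckle it produces fluctuate: the intensity
autocorrelation `g2(tau) = <I(t) I(t+tau)> / <I>^2` decays faster when red
blood cells move faster. Fitting the decay with the semi-infinite
correlation diffusion model (via the Siegert relation
`g2 = 1 + beta * g1^2`) yields a blood flow index, BFi (cm²/s). Whether a
DCS instrument can detect a *cerebral* flow change through the scalp and
skull depends on wavelength: at 1064 nm, tissue attenuation
(`mueff = sqrt(3 mua (mua + musp))`) is lower, skin-exposure limits permit
more power, and each milliwatt carries more photons — together roughly an
order of magnitude more detected photons than at 765 nm, which translates
into dramatically better detection statistics for deep flow changes.

`dcsim` implements that whole argument as a reusable, tested pipeline:

- **Tissue optics** — chromophore absorption from bundled extinction
  spectra, scattering power law `musp = a (lambda/500)^(-b)`, and a
  randomized population study over physiological parameter ranges
  (`tissue_optical_properties()`, `sample_tissue_population()`).
- **Photon budget** — ANSI skin-exposure limits, permitted power, photons
  per unit energy, and attenuation-driven detected-intensity gain
  (`photon_budget()`).
- **Correlation models** — semi-infinite correlation-diffusion `g1`,
  Siegert `g2`, and deterministic BFi fitting with broom-style `tidy()` /
  `glance()` methods (`simulate_g2()`, `fit_bfi()`).
- **Noise synthesis** — lag-dependent correlator noise from the
  photon-counting estimator-variance model, multi-fiber averaging, seeded
  frame sequences (`g2_noise_std()`, `synthesize_g2_sequence()`).
- **Monte Carlo transport** — a layered-slab white Monte Carlo (Rcpp) with
  per-layer pathlength and momentum-transfer tallies; absorption and
  per-layer BFi are applied analytically afterwards, so one transport run
  serves a whole flow sweep (`run_photon_mc()`, `g1_from_records()`).
- **Detection power** — the two-layer head scenario: noisy 1-s frames,
  per-frame fits, six 10-frame segments, 36 paired Welch tests at
  alpha = 0.05, detection probability versus imposed deep-flow change
  (`study_design()`, `run_detection_power_study()`).

## Worked example

```r
library(dcsim)

# optical properties of a reference brain-like tissue
tissue <- data.frame(hbt_uM = 80, so2 = 0.625, f_water = 0.75, f_fat = 0.2,
                     a = 20, b = 1.5)
tissue_optical_properties(tissue, c(765, 1064))
#>   ... mua 0.190 / 0.180 cm^-1, musp 10.6 / 6.44 cm^-1, mueff 2.48 / 1.89 cm^-1

# the three photon-budget factors of 1064 nm vs 765 nm at 3 cm separation
photon_budget(wavelength_nm = 765)
#>   permitted_power_mW 26.0 (vs 103 at 1064 nm), energy_ratio 3.96,
#>   photons_per_energy_ratio 1.39, intensity_ratio 1.98, combined_gain 10.9

# simulate a 1064-nm measurement, add correlator noise, fit it back
geo   <- dcs_geometry(rho_cm = 3, wavelength_nm = 1064)
clean <- simulate_g2(geo, mua = 0.18, musp = 6, bfi = 2e-8)
noisy <- add_g2_noise(clean, noise_settings(42500, t_int_s = 10), seed = 7)
glance(fit_bfi(noisy, geo, mua = 0.18, musp = 6))
#>   bfi ~ 2.0e-08 cm^2/s, converged TRUE
```

The numbers mean: at the regulatory power limit, a 1064-nm system delivers
~4x the power and ~1.4x the photons per unit energy of a 765-nm system, and
its lower attenuation leaves ~2x as many photons at a 3-cm detector —
about an 11-fold photon advantage, which is why its fitted BFi time series
is clean enough to resolve a 20% cerebral flow change in a pair of 10-s
measurements.

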