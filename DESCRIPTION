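Package: dcsim
Title: Simulation Toolkit for Long-Wavelength Diffuse Correlation Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-simulation pipeline for continuous-wave diffuse correlation
    spectroscopy (DCS) across near-infrared wavelengths. Models tissue optical
    properties from chromophore composition and a scattering power law, accounts
    for the photon budget permitted under ANSI skin-exposure limits, synthesizes
    intensity autocorrelation (g2) curves with a lag-dependent correlation noise
    model, runs a layered-slab white Monte Carlo with per-layer pathlength and
    momentum-transfer tallies, fits blood flow indices (BFi) with the semi-infinite
    correlation diffusion model, and estimates the statistical power for detecting
    deep (cerebral) blood-flow changes at a given count rate and wavelength.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
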