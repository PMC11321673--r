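Package: polarsmoke
Title: Polarization-Difference Desmoking for Linear Polarimetric Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Restoration of images degraded by surgical smoke and similar
    scattering media from four linearly polarized channels (0/45/90/135
    degrees). Implements the polarization-based degradation model, direct
    and refined polarization-difference (PD) estimators of the backscattered
    component, ambient-light and transmission-map estimation, and
    channel-by-channel scene recovery. Ships a Lorenz-Mie single-sphere
    solver, a Stokes-tracked polarized Monte Carlo photon transport model of
    a smoke-over-surface slab used to derive the electric-field-direction
    prior, the cosine-squared weight-curve fit that yields the refined-PD
    coefficients, a synthetic polarized-smoke scene generator, and
    full-reference image quality metrics (PSNR, SSIM, CIEDE2000).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
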