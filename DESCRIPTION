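Package: stratoc
Title: Stratospheric Aerosol Effects on Satellite Ocean-Color Retrievals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how enhanced stratospheric aerosol loading
    biases satellite ocean-color retrievals. Provides a layered single-scattering
    top-of-atmosphere reflectance simulator with explicit gas-absorption ordering
    and a first-order scattering-absorption coupling term, a NASA-style
    atmospheric correction (full-column gas correction, Rayleigh subtraction,
    near-infrared aerosol model selection) that deliberately assumes all aerosol
    lies below the ozone layer, semi-analytical bio-optical forward and inverse
    models (color-index chlorophyll and spectral-optimization particulate
    backscattering), Mie optics of lognormal aerosol size distributions,
    band-integrated gas transmittances, regional climatology and standardized
    anomaly pipelines for gridded ocean-color and stratospheric aerosol optical
    thickness fields, a BGC-Argo style backscattering quality-control chain, and
    seeded synthetic-data generators so every pipeline is testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
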