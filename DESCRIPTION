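Package: bladderdose
Title: Light Dosimetry for Photodynamic Therapy of Hollow Organs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monte Carlo light-transport simulation and dosimetry analysis
    for intracavitary photodynamic therapy (PDT), with the urinary bladder
    as the target organ. Provides a synthetic generator for closed,
    star-shaped bladder cavities with a finite-thickness wall and an
    adipose backing layer; a photon-packet transport engine with
    Henyey-Greenstein scattering, absorption weighting and refractive-index
    boundaries; dose-surface-histogram (DSH) construction and comparison;
    virtual irradiance-sensor models (single cut-end fiber, triple
    angled-cut fibers, and a twelve-sensor cage) with treatment monitoring
    by radiant-exposure integration; and a photodynamic-threshold
    selectivity model linking photosensitizer uptake ratios and tissue
    threshold doses to achievable treatment depth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
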