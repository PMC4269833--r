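Package: chiralflow
Title: Thin-Film Active Chiral Fluid Analysis of Cortical Flow
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the actomyosin cell cortex as a thin film of an active
    chiral fluid and quantifies chiral cortical flow in early C. elegans
    embryos. Solves the coupled axial/chiral flow equations driven by a
    myosin intensity profile, fits the hydrodynamic length and the
    chirality index to measured velocity profiles with Hessian-based
    uncertainties, and provides the accompanying quantification toolbox:
    AP-binned velocity profiles, chiral counter-rotation velocities at the
    1-cell and 4-cell stages, 3D division-axis skew angles, myosin foci
    size by spatial autocorrelation, and fully deterministic synthetic-data
    generators for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
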