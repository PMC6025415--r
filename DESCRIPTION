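Package: cdomPAE
Title: Fluorescence Regional Integration of CDOM and Phthalate Exposure
    Risk in Lake Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing chromophoric dissolved organic matter
    (CDOM) optics alongside phthalate acid ester (PAE) contamination in
    lake surveys. Implements excitation-emission matrix (EEM)
    preprocessing (blank subtraction, Rayleigh/Raman scatter excision,
    inner-filter correction), five-region fluorescence regional
    integration (FRI) with fluorescence source indices, CDOM absorption
    metrics (Napierian absorption coefficients, spectral slopes,
    E250:365, SUVA254), USEPA-style non-cancer and carcinogenic risk
    assessment for DMP/DEP/DBP via the drinking-water route, and the
    correlation and regression layer that evaluates FRI components as
    optical predictors of PAE concentrations. A seeded synthetic-survey
    generator emulates a two-season 45-sample campaign so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'absorption.R'
    'association.R'
    'cdomPAE-package.R'
    'dataio.R'
    'fri.R'
    'pipeline.R'
    'preprocess.R'
    'risk.R'
    'synthetic.R'
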