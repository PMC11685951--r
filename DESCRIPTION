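Package: srisoscape
Title: Bioavailable Strontium Isoscapes and Isotope-Based Geographic Assignment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds bioavailable 87Sr/86Sr isoscapes from georeferenced point
    measurements and gridded environmental predictors using bagged
    regression-tree ensembles, with per-cell prediction standard errors from
    the infinitesimal jackknife for bagging, strict-extrapolation masking and
    Mahalanobis environmental-similarity (mobility-oriented parity) surfaces.
    Provides continuous-surface geographic assignment of individuals from
    tissue isotope values, single isotope (87Sr/86Sr) or dual isotope
    (87Sr/86Sr with carbonate d18O converted to drinking water), with region
    priors, credible-region utilities, residual and spatial-autocorrelation
    diagnostics, and a synthetic-landscape generator for end-to-end testing
    with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ranger,
    geosphere,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
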