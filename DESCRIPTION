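Package: geomort
Title: Ecological Regression of Areal Cancer Mortality on Kriged Topsoil
    Geochemistry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline linking point-sampled topsoil
    heavy-metal concentrations to area-level cancer mortality. Element
    concentrations are interpolated to area centroids by ordinary kriging,
    transformed to centred log-ratios, and reduced to latent exposure
    factors by robust principal factor analysis with varimax rotation.
    Factor scores then enter a Bayesian Poisson ecological regression with
    expected deaths as offset and Besag-York-Mollie spatial random
    effects, yielding relative risks with 95 percent credibility
    intervals. A synthetic-data module generates geochemical fields,
    areal lattices and mortality counts with known parameters so every
    stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
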