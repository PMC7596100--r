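Package: immunospat
Title: Spatial Statistics and Likelihood Inference of Immune Cell
    Infiltration in Tumour Point Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies immune-cell infiltration into tumour cell nests from
    2-D point patterns of cell centroids. Computes the pair correlation
    function with rectangular edge correction, the nearest-neighbour and
    spherical contact distributions and the J-function, and reduces each
    pattern to three summary features (peak clustering intensity, largest
    empty-circle radius and clustering depth). Generates synthetic
    two-compartment tumour/stroma point patterns from thresholded Gaussian
    random fields with a hard-core exclusion and a tunable infiltration
    ratio, fits exponential feature-response curves, and infers the
    infiltration ratio with profile-likelihood confidence intervals from
    any subset of the three features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
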