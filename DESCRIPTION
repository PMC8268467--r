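Package: phiclass
Title: Classification of Compositional Samples by Correlation-Structure
    Distortion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-group (control versus case) classification of samples from
    compositional count tables such as 16S rRNA OTU tables.  New samples are
    assigned to the group whose correlation structure they distort the least,
    as measured by a spectral distortion metric (phi) computed from the
    eigendecomposition of the group correlation matrix before and after the
    sample is incorporated.  The incorporation uses an exact rank-one update
    of the mean vector, standard deviations and correlation matrix, combined
    with an artificial dimensional reduction that re-weights the influence of
    the new sample.  Includes centered log-ratio pretreatment with
    Bayesian-multiplicative zero replacement, a Gaussian simulator based on
    equicorrelation generatrix matrices, and a Monte-Carlo accuracy harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
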