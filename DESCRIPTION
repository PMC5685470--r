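Package: refframe
Title: Reference-Frame Analysis of Visual and Vestibular Heading Tuning
Version: 0.1.0
Authors@R:
    person("Morgan", "Hale", email = "morgan.hale@example.org",
           role = c("aut", "cre"))
Description: Tools to determine the spatial reference frame (eye- versus
    head-centered) of heading-tuned neurons from trial-level firing rates.
    Implements the cross-covariance displacement index with bootstrap
    confidence intervals and four-way classification, the three-step
    partial-shift analysis of tuning under smooth pursuit, joint
    wrapped-Gaussian model fitting across eye positions with
    partial-correlation model comparison, eye-position gain-field
    quantification, and heading-estimation behavioural analysis. A
    synthetic-data generator with a continuous eye-vs-head frame parameter
    makes every stage verifiable by parameter recovery without neural
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
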