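Package: gzpkin
Title: Dynamic Granzyme-B PET Pharmacokinetic Modeling and Response Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of dynamic granzyme-B-targeted PET in
    preclinical glioblastoma: frame-schedule handling, decay correction and
    standardized-uptake-value (SUV) conversion, region-of-interest
    time-activity-curve extraction from 4D images, multi-exponential fitting
    of an image-derived arterial input function, forward simulation and
    bounded multi-start nonlinear-least-squares inversion of nested one-,
    two- and three-tissue compartment models, Akaike-information-criterion
    model selection, tumor-to-background and longitudinal response metrics,
    and the accompanying statistical layer (Grubbs outlier screening,
    Welch and paired t tests, Geisser-Greenhouse-corrected repeated-measures
    ANOVA with Tukey pairwise tests, Pearson correlation). A synthetic
    phantom generator produces cohorts with known ground-truth kinetics so
    parameter recovery and model selection are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    car,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
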