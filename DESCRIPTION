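Package: sonoskill
Title: Quantitative Assessment of Ultrasound Image-Acquisition Competence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Assesses the competence of trainees acquiring point-of-care
    ultrasound images from the clinical measurements obtained from those
    images. Fits a three-level Bayesian mixed-effects model (readings nested
    in images nested in patients) by Gibbs sampling with diffuse priors,
    partitioning each trainee's acquisition error into a systematic component
    (a fixed-effect shift relative to instructor-acquired images, in mm) and
    a sporadic component (excess image-to-image variance, in mm^2). Errors
    are judged against measurement-theory equivalence and noninferiority
    zones derived from the instructor's images, yielding a traffic-light
    verdict per trainee and diameter type, together with consistency
    intraclass correlation coefficients. Includes a synthetic-data generator
    for the contemporaneous-acquisition study design, forest-plot graphics,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
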