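Package: ahazmed
Title: High-Dimensional Mediation Analysis for Survival Outcomes Under
    the Additive Hazards Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Identifies and tests high-dimensional mediators (for example
    DNA methylation markers) lying on the pathway between an exposure and
    a right-censored survival outcome, using the additive hazards model.
    Implements sure independence screening, SCAD-penalized Lin-Ying
    least-squares-type estimation with cross-validated tuning, Sobel
    tests of indirect effects with Benjamini-Hochberg or
    Benjamini-Yekutieli false-discovery-rate adjustment, and the
    decomposition of the total exposure effect into direct and indirect
    parts.  A built-in simulator generates data from the same additive
    hazard design used to validate the procedure and scores selection and
    estimation performance over replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
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
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
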