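Package: beatkit
Title: Beating Kinetics and Calcium Transient Analysis for Cultured
    Cardiomyocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies the spontaneous contractile activity of beating
    cardiomyocyte monolayers from brightfield microscopy video using
    exhaustive block-matching motion estimation with a Mean Absolute
    Difference criterion, and derives beat kinetics (beating frequency,
    beating velocity, maximum displacement, beat area, baseline-normalized
    recovery). Extracts calcium-transient kinetics (time-to-peak, APD50,
    APD90, triangulation) from Fluo-4 intensity traces and compares
    pre/post drug recordings. Includes a synthetic-data generator with
    known ground truth for end-to-end validation, and the group-comparison
    statistics (one-way ANOVA with Tukey's post hoc test) used to report
    results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
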