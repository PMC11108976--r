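Package: scovnet
Title: Structural Covariance Network Analysis of Amygdala Subnuclei
Version: 1.0.0
Authors@R:
    person("scovnet", "maintainers", email = "scovnet@example.org",
           role = c("aut", "cre"))
Description: Covariate-adjusted structural covariance analysis of regional
    gray-matter volume tables: per-subnucleus covariance profiles,
    within-group comparison of dependent overlapping correlations
    (Dunn & Clark z with Zou confidence intervals), between-group Fisher
    z comparisons, layered FDR + Bonferroni multiple-testing control,
    density-thresholded binary covariance graphs with nodal degree,
    betweenness and clustering, Hirschberger-Qi-Steuer null covariance
    matrices, permutation inference integrated across the density sweep,
    covariate-adjusted volume comparisons, and a synthetic-cohort
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
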