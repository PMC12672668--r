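Package: bodymds
Title: Measuring Body-Ownership Illusion Strength with Inverse Multidimensional Scaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring the strength of body-ownership illusions
    (such as the rubber hand illusion) from multi-arrangement similarity
    data. Estimates representational dissimilarity matrices from repeated
    item arrangements with adaptive subset selection (inverse
    multidimensional scaling), fits interval MDS solutions by SMACOF
    majorization with Kruskal stress-1 diagnostics and permutation
    benchmarks, aligns configurations across conditions by Procrustes
    analysis, and derives ownership scores and baseline-anchored distance
    indices of illusion strength, together with paired comparisons, power
    planning, k-means structure analysis, and a synthetic-participant
    simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
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
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
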