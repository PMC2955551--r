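Package: aimtools
Title: Ancestry-Informative Marker Selection and Admixture Estimation
    from Multi-Allelic Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating panels of ancestry-informative
    microsatellite markers. Implements the multi-allelic Weir-Cockerham
    F_st estimator (per-locus variance components, ratio-of-sums multi-locus
    theta, pairwise population matrices), Bayesian admixture clustering by
    Gibbs sampling with inferred Dirichlet admixture parameters, Evanno-style
    delta-K model selection over replicate runs, label-switching alignment
    and averaging of replicate membership matrices, presence/absence
    ("false SNP") re-coding with principal component analysis, F_st-ranked
    panel reduction, Balding-Nichols genotype simulation with admixed
    cohorts, and cohort-level ancestry-proportion reporting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
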