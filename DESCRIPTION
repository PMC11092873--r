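Package: halfloopr
Title: Covariate-Corrected Half-Loop Biclustering of Case/Control Genotype Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of disease-specific genetic subgroups (biclusters) in
    case/control genotype data using the covariate-corrected half-loop
    algorithm: one-hot allele-combination encoding of diploid genotypes,
    iterative row/column elimination driven by case-versus-control sharing
    scores, covariate-stratified label-permutation significance, cross-cohort
    replication via projection onto the bicluster's dominant principal
    component, bicluster-informed polygenic risk scores with greedy LD
    clumping and p-value thresholding, liability-scale R2 conversion of AUCs,
    and gene-set over-representation of the retained allele-combinations.
    Includes a deterministic multi-arm synthetic cohort generator with
    planted biclusters for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
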