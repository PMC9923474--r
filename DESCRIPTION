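Package: ibdkernel
Title: Larval Dispersal Kernel Spread from Isolation-by-Distance Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the spread of a larval dispersal kernel from
    microsatellite genotypes sampled along an approximately one-dimensional
    coastline. Implements Genepop input/output, Weir-Cockerham pairwise
    F_ST, Hardy-Weinberg exact tests, Mantel and partial Mantel permutation
    tests, ordinary least-squares isolation-by-distance regression, the
    linkage-disequilibrium estimator of the effective number of breeders
    with an overlapping-generations adjustment, Rousset's one-dimensional
    sigma estimator with Monte-Carlo error propagation, visual-census
    linear density with BCa bootstrap intervals, and comparisons of genetic
    distance against modeled larval connectivity. A forward-time
    stepping-stone simulator with stepwise-mutating microsatellites
    provides ground-truth data for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    boot,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
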