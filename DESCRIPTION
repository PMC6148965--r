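Package: DESyn
Title: Differential Expression Analysis for Syndromes by Testing Mean and
    Dispersion Simultaneously
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects differentially expressed genes between a normal and a
    disease group in RNA-seq count data when afflicted individuals may each
    carry a different combination of expression aberrations, as in overgrowth
    syndromes. Implements a negative-binomial likelihood ratio test of
    simultaneous change in mean and dispersion, empirical-Bayes shrinkage of
    per-gene dispersion estimates toward genome-wide normal hyperpriors, a
    pooled permutation null distribution for the shrunken statistic, Storey
    q-value false discovery rate control, and per-replicate classification of
    differentially expressed genes via negative-binomial prediction intervals
    with Bonferroni family-wise error control. Includes TMM normalization,
    a mean-only negative-binomial likelihood ratio baseline, and a simulation
    framework with ground-truth ledgers for power and FDR benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
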