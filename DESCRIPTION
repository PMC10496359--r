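Package: coevotest
Title: Detecting Natural Selection on Trait-Trait Coevolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tests whether natural selection has shaped the coevolution of
    phenotypic trait pairs by comparing mutational correlations (estimated
    across mutant panels) with evolutionary correlations (estimated across
    phylogenetically related lineages via independent contrasts). Provides the
    Fisher r-to-Z comparison with Benjamini-Hochberg false discovery rate
    control and classification of significant pairs as evolutionarily
    strengthened, weakened, or reversed; neutral Brownian-motion nulls for
    significant-pair counts; eigenvalue-variance integration and
    covariance-ratio modularity statistics with rank-matched subsampling
    nulls; forward origin-fixation simulation of two-trait evolution under
    Gaussian ridge, point-optimum, and random-optima selection with optional
    mutational bias; and synthetic-data generators emulating mutant panels and
    divergence data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
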