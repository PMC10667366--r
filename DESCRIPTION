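Package: mtlgwas
Title: Multi-Trait Longitudinal Genome-Wide Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fast genome-wide association analysis for multiple correlated
    longitudinal traits. Fits a multivariate linear mixed model with
    per-individual random intercepts and slopes for K traits jointly, using a
    Kronecker-structured residual and genetic covariance, a recursive
    block-partitioning algorithm for inverting the random-effects coefficient
    block, and a bordered transformed system so that each variant requires
    solving only for its own 2K cross-sectional and longitudinal effects.
    Variance components are assembled from pairwise bivariate AI-REML fits.
    Includes a stochastic simulation framework for power and type-I-error
    evaluation, a single-trait reduction, and a rate-of-change GWAS
    comparator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    jsonlite
Config/testthat/edition: 3
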