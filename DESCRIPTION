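Package: igemate
Title: Direct and Indirect Genetic Effects on Dyadic Mating Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative-genetic analysis of mate-choice behaviour expressed
    in male-female dyads. Provides pedigree handling and numerator
    relationship matrices (with inbreeding), a restricted maximum likelihood
    (REML) animal model that partitions variance in dyadic traits into direct
    and indirect genetic effects (DGEs and IGEs) plus permanent-environment
    and residual components, within- and cross-sex genetic correlations from
    bivariate fits, boundary-aware likelihood-ratio tests, total heritable
    variance for dyads, the genetic-level psi (responsiveness) matrix, and a
    synthetic-data generator that emulates a paternal half-sib breeding
    design with sequential mating trials so the whole pipeline can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
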