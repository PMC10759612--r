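Package: larchgp
Title: Genomic Dissection of Additive and Non-Additive Effects in
    Open-Pollinated Forest Progeny Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for partitioning phenotypic variance of open-pollinated
    forest-tree progeny trials into additive, dominance, imprinting
    (parent-of-origin) and additive-by-additive epistatic components, and for
    genomic prediction. Builds pedigree-based (A) and marker-based (G)
    relationship matrices including dominance, imprinting and Hadamard
    epistatic matrices, fits multi-kernel linear mixed models by AI-REML with
    positively constrained variance components, fits Gaussian-kernel RKHS
    regressions by Gibbs sampling, and assesses predictive ability by
    replicated k-fold cross-validation. A synthetic-data generator emulating
    an open-pollinated progeny trial (phased genotypes, randomized complete
    block field layout, multi-component phenotypes) makes the whole pipeline
    testable without access to trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    vcfR,
    knitr
Config/testthat/edition: 3
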