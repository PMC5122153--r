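Package: liabscan
Title: Threshold Liability Models and CNV Region Association for Bovine
    Embryonic Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the quantitative-genetic dissection of binary
    fertility traits in cattle and the copy-number variants that affect
    them. Implements a Bayesian threshold liability animal model for
    repeated binary return-to-estrus records fitted by Gibbs sampling
    with liability data augmentation, pedigree (numerator) and genomic
    (VanRaden) relationship matrices, construction and filtering of CNV
    regions from per-animal calls, a mixed-model association scan with
    genomic-control and Bonferroni multiple-testing control,
    sequence-level characterization of deletions arising by non-allelic
    homologous recombination (homology arms, breakpoint ambiguity,
    transcript consequences), qPCR delta-delta-Ct copy-number
    estimation, and replication/effect-size statistics. A synthetic
    cohort generator reproduces the statistical structure every stage
    assumes so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    jsonlite,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
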