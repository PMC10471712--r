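Package: rrgsim
Title: Stochastic Simulation of Reciprocal Recurrent Genomic Selection in Hybrid Breeding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time stochastic simulation of reciprocal recurrent
    genomic selection (RRGS) for hybrid breeding between two heterotic pools.
    Generates divergent founder pools of homozygous lines with realistic
    linkage disequilibrium, samples quantitative trait architectures with
    additive and dominance effects, simulates meiosis on a genetic map,
    builds genomic relationship matrices with population-specific allele
    frequency centring, estimates variance components by restricted maximum
    likelihood, and computes GBLUPs for testcross performance (half-sib
    training) or general combining ability (full-sib factorial training).
    Tracks cumulative selection gain, GCA and SCA variance dynamics, genic
    variances and the Bulmer effect, prediction accuracy, and modified
    Rogers' distances over multiple selection cycles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
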