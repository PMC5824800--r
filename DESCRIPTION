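Package: protocode
Title: Iterated-Learning Simulation of Genetic Code Evolution by
    Horizontal Transfer
Version: 0.1.0
Authors@R:
    person("Protocode", "Maintainers", email = "maintainers@protocode.dev",
           role = c("aut", "cre"))
Description: Agent-based simulator of the communal (horizontal-transfer-only)
    origin of the genetic code. Each protocell carries a 'black box'
    translation system, a 3-6-11 logistic multilayer perceptron mapping codons
    to points in an 11-dimensional amino-acid chemical space. Protocells
    repeatedly exchange small code fragments (obverter-chosen codon /
    amino-acid pairs, sampled by cellular amino-acid abundance) which the
    receiver assimilates by backpropagation, so codes evolve without any
    vertical descent, fitness, or selection. Includes the standard genetic
    code as a fixed comparator, the polar-requirement error-robustness score
    for codon tables, population universality and expressivity measures,
    regularity analyses of evolved codes, and a command-line interface for
    running, scoring and analysing simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
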