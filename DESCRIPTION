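Package: repeatpotts
Title: Maximum-Entropy Potts Models and Sequence-Space Entropy for Repeat
    Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits maximum-entropy Potts models with an explicit
    repeat-overlap constraint to alignments of pairs of consecutive protein
    repeats, estimates family sequence entropies by thermodynamic
    integration of Monte-Carlo simulations, characterizes the multi-basin
    structure of the statistical energy landscape by zero-temperature
    quenches, and compares families by Kullback-Leibler divergence. Includes
    a planted-model synthetic data generator so every stage of the analysis
    can be validated against exact enumeration oracles at desk scale.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
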