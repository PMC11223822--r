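Package: framehmm
Title: Frameshift-Aware Translated Profile HMM Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Translated homology search of DNA against protein profile hidden
    Markov models that tolerates frameshift-inducing indels. Queries (protein
    alignments, single sequences, or profile files) are compared to six-frame
    translations of the target DNA through a staged filter pipeline (MSV,
    Viterbi, dual Forward), and candidate regions are rescored with a
    frameshift-aware codon-space Forward algorithm in which match states emit
    codons, stop codons, or length 1-5 quasi-codons. Scores are calibrated by
    simulation to exponential/Gumbel tails and reported with E-values. A
    synthetic benchmark generator (pseudochromosomes, reverse-translated
    decoys, indel-mutated family instances) and evaluator (ROC, recall-0,
    coverage, overextension, E-value accuracy) are included.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    tibble,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
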