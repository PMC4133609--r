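Package: profalign
Title: Structure-Augmented Pairwise Profile Hidden Markov Model Alignment
Version: 0.1.0
Authors@R: person("profalign", "developers", role = c("aut", "cre"),
    email = "profalign@example.org")
Description: Pairwise alignment of two protein profile hidden Markov models
    by Viterbi and maximum-accuracy (MAC) decoding, with match-state scores
    augmented by secondary-structure, solvent-accessibility and backbone
    torsion-angle agreement, and a final traceback optionally guided by
    evolutionary residue-coupling (mutual information) constraints. Includes
    profile construction from multiple sequence alignments, structural
    annotation parsing, SP/TC alignment benchmarking against reference
    alignments with core blocks, and a seeded synthetic homolog-pair
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
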