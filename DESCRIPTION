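Package: rcstore
Title: Random-Code Codec for DNA Data Storage
Version: 0.1.0
Authors@R:
    person("Alex", "Moreau", email = "alex.moreau@example.org", role = c("aut", "cre"))
Description: Encoder and decoder for DNA data storage built on seeded random
    binary generator matrices over GF(2) ("random code"). Files are split into
    K fixed-width chunks, combined into droplets by the rows of a randomly
    drawn (K+m) x K generator matrix selected by Gaussian XOR-elimination
    preprocessing, balanced against biological sequence constraints
    (homopolymer runs, GC content, micro-satellites) by iterative XOR masking
    ("random equilibrium"), and assembled into fixed-layout oligonucleotide
    strands with an XOR checksum. Includes analytic run-length (Feller) and
    degree-distribution models, an insertion/deletion/substitution/loss
    channel simulator, a Luby-transform (LT) fountain-code baseline with
    ideal and robust soliton distributions, FASTA/JSON manifest I/O and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
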