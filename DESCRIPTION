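Package: taec
Title: Taxonomic Abundance Estimation by Elimination and Correction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Homology-based estimation of genome relative abundance in
    metagenomic samples from read-alignment results. Genomes whose alignment
    hits are explainable by the presence of similar genomes are removed by a
    greedy unique-read elimination procedure with non-parametric bootstrap
    filtering; read counts of the surviving genomes are then corrected by
    inverting a genome-similarity linear system. Includes a builder for the
    genome-similarity matrix (simulated reads, alpha-threshold multi-assignment),
    a synthetic community and read simulator with a built-in k-mer seed aligner
    for end-to-end testing without external tools, and the standard relative
    error measures (RRMSE, AVGRE, MAXRE) for benchmarking against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
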