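Package: nemamp
Title: Pan-Phylum Mining and Classification of Nematode Antimicrobial Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico discovery pipeline for the five known nematode
    antimicrobial peptide (AMP) groups (Cecropin, Diapausin, CSab defensin-fold
    peptides, Nemapore and glycine-rich secreted peptides) from predicted
    proteomes. Provides lightweight profile-model homology search with
    Gumbel-calibrated E-values, Smith-Waterman local alignment, iterative
    query expansion to convergence, cysteine-array motif matching and
    subgroup classification, rule-based signal peptide and furin propeptide
    maturation, per-genome repertoire statistics with nonparametric tests,
    life-stage expression summaries, and a synthetic proteome generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
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
    withr,
    nortest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
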