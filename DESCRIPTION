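Package: protruler
Title: Histone-Ruler Copy-Number Proteomics and T Cell Proteome Remodelling Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates absolute protein copy numbers and protein mass per cell
    from label-free quantitative proteomics intensity tables using the histone
    "proteomic ruler", which anchors total histone MS signal to the histone mass
    implied by a diploid cell's DNA content. Implements the standard filtering
    rules for search-engine protein-groups tables (contaminant/reverse/site
    decoys, replicate detection filters, peptide-count quality categories),
    Welch two-sample tests on log2 copy numbers with fold-change based
    regulation classes, and proteome-structure analytics: cumulative mass-rank
    profiles, gene-set mass fractions, and min-max scaled heatmap matrices
    ordered by correlation clustering. Ships a synthetic-data generator that
    plants known copy numbers, effect classes, histones and decoy rows so that
    every stage of the pipeline can be validated against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
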