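Package: homeoclass
Title: Homeobox Gene Discovery, Classification and Gain/Loss Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for surveying homeobox gene
    complements in transcriptomes and genome assemblies. Implements
    recursive Smith-Waterman homeodomain discovery run to search
    saturation, TALE-class loop-extension typing, two-homeodomain
    architecture calls, neighbor-joining phylogenies with nonparametric
    bootstrap, bipartition-based transfer of support values across
    phylogenies, criterion-based clade calling reconciled against a
    persistent nomenclature registry, alignment conservation analyses
    (identity masks, unique-variant positions, motif scans), and minimum
    gain/loss reconstruction of gene families on a species cladogram
    under Dollo parsimony. A seeded gene-family simulator with full
    ground truth makes every stage testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    tibble,
    tidyr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
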