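Package: lustar
Title: Discovery and Classification of Three-Finger (LU-Domain) Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for finding and classifying three-finger
    proteins (Ly6/uPAR family) in proteomes. Curates reference LU-domains by
    their conserved 8-10-cysteine scaffold, searches a proteome with exact
    affine-gap Smith-Waterman local alignment scored under a
    cysteine-anchored BLOSUM62 variant (C/C = 99, C/x = -4) with
    Karlin-Altschul bit scores and E-values, builds a neighbor-joining guide
    tree, computes a progressive multiple alignment that pins homologous
    cysteines into shared columns, and scores pairwise relatedness with a
    grouped-residue (hydrophobic/cysteine/polar/positive/negative) percent
    similarity. Includes disulfide-corrected average protein mass, in-silico
    PCR, and a synthetic-data generator of decoy proteomes with planted
    LU-domain homologs so the whole pipeline is exercisable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    phangorn,
    purrr,
    Rcpp,
    readr,
    rlang,
    seqinr,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
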