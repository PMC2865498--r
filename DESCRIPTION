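Package: degradomics
Title: Homology-Driven Annotation and Comparative Analysis of Protease Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating the degradome (the full protease and
    protease-like gene complement) of a genome by homology to a curated seed
    set, and for comparing degradomes across species. Implements a translated
    homology search (six-frame translation, k-mer seeding, gapped X-drop
    extension under BLOSUM62, Karlin-Altschul E-values), an iterative
    annotate-tune loop that chains high-scoring pairs into multi-exon gene
    models and refines exon boundaries at GT/AG splice signals, reciprocal
    best hit orthology with tandem-duplication and family-expansion calls,
    catalytic-residue inspection for non-peptidase-homolog classification,
    and bootstrap Fitch-parsimony phylogenetics with majority-rule consensus.
    A synthetic-genome forge implants protease genes with known duplication,
    loss and pseudogenization histories so that every stage can be validated
    against an exact truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
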