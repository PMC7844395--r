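Package: fibrotalk
Title: Shared Functional Features and Gene Cross-Talk Across Fibrotic Diseases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for discovering genes and functional pathways
    shared across fibrotic diseases of different organs. Genes are encoded as
    functional profiles of -log10 hypergeometric enrichment scores computed
    from their neighborhoods in a confidence-weighted functional-association
    network against GO/KEGG-style gene-set catalogs; disease-discriminating
    features are ranked by Monte Carlo feature selection over random-projection
    decision trees with a permutation significance cutoff; overlaps among
    disease gene lists are quantified with exact multi-set intersection
    statistics (probability mass function, expectation, fold enrichment and
    tail p-values over all set combinations); and cross-talk subnetworks
    between disease pairs and their shared functional terms are extracted.
    A synthetic-data module generates networks, annotation catalogs and
    disease-gene matrices with planted, recoverable signal so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
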