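Package: gtproot
Title: Rooting Species Trees by Gene Tree Parsimony with a Duplication-Loss Criterion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Duplication-loss reconciliation of multi-copy unrooted gene trees
    against rooted species trees (LCA mapping, event labelling, loss counting,
    optimal gene-tree rooting), replicated heuristic search for the
    minimum-cost rooted species tree, constrained evaluation of named root
    hypotheses with rank-based statistics, gene-family selection filters, and
    a duplication-loss gene-family simulator with clade-biased missing data
    for studying the missing-data/loss confound in gene tree parsimony.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
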