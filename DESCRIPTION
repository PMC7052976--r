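Package: gcdollo
Title: Comparative Gene-Content Analysis with Dollo Parsimony
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of gene-content (presence/absence)
    data across species, built around KEGG Orthology annotation tables and a
    rooted species phylogeny. Implements construction and validation of binary
    presence/absence matrices, group-level presence calls and exclusive
    (UpSet-style) intersections, a convergent-loss screen, Dollo-parsimony
    mapping of per-feature gains and losses onto the tree with per-node
    category summaries, Hamming-distance UMAP embedding with a parameter sweep
    and a quantitative seed-stability protocol, and the rule-based
    sequence-level filters used in euglenozoan comparative transcriptomics:
    taxonomic best-hit decontamination, divergent-homolog acceptance
    (E-value, p-distance, splice-leader, domain-extension rules), and
    centromeric-histone (cenH3/H3V) candidate classification. A synthetic-data
    module simulates single-gain/branchwise-loss evolution, transcriptome
    dropout, homology-hit tables, and histone-like alignments so that every
    stage can be exercised and benchmarked without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    mclust,
    stats,
    utils,
    uwot
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
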