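Package: pathdevfate
Title: Stage-Specific Developmental Gene Screening and Regulatory Pathway
    Extraction Along Cell Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies stage-specific developmental genes from expression
    profiles along a cell differentiation lineage, integrates them into a
    lineage-specific expression pattern, screens the full matrix for genes
    following that pattern by Spearman rank correlation, assembles a
    TF-target regulatory subnetwork from a curated interaction table
    (TRRUST dialect), and extracts a connected regulatory pathway of
    high-in-degree influencer genes joined by a minimal set of Steiner
    connector TFs. Includes a column-permutation Jaccard test for the
    significance of the correlated gene set, a synthetic-data generator
    with planted ground truth, and monotone tree rules for branched
    lineages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
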