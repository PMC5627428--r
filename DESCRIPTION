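Package: famkit
Title: Species-Tree-Aware Gene Family Tree Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for analysing gene family trees against a known species
    tree. Implements species-overlap classification of gene-tree nodes into
    speciations and duplications, detection of paralog-generating nodes and
    splitting of a gene family tree into ortholog sets, duplication-aware
    average normalized Robinson-Foulds distance between a gene family tree
    and a species tree, LCA-mapping duplication/loss reconciliation,
    maximum-clade-credibility summarization of posterior tree samples, and a
    birth-death duplication-loss-transfer simulator of gene family evolution
    along a dated species tree with ground-truth event logs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
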