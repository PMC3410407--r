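Package: ktfam
Title: Genome-Wide Inventory of Plant Potassium Transporter Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for building genome-wide inventories of plant potassium
    transporter and channel families (HAK/KT/KUP, HKT, tandem-pore and
    Shaker-like channels). Implements degenerate protein motif screening of
    proteomes, semi-automatic curation by length and pairwise-identity
    filtering, six-frame G-Y-G selectivity-filter scans of genomic DNA,
    progressive multiple alignment with conserved-block filtering,
    distance-based phylogenetics (UPGMA, neighbor joining, bootstrap), and
    gene-tree/species-tree reconciliation under duplication-loss parsimony
    with ancestral copy-number reports. A birth-death simulator of gene
    families evolving along a species tree provides fully labelled synthetic
    proteomes so every pipeline stage can be tested without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    ape,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    phangorn,
    phytools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
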