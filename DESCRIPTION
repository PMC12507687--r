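Package: ancora
Title: Ancestral Gene Order Reconstruction from Hierarchical Orthologous Groups
Version: 0.1.0
Authors@R:
    person("ancora", "developers", email = "ancora@example.org", role = c("aut", "cre"))
Description: Reconstructs ancestral gene order along a rooted species tree from
    extant gene coordinates (GFF3) and hierarchical orthologous groups
    (OrthoXML). Extant gene adjacencies are propagated bottom-up along gene
    lineages, filtered top-down by a Dollo-style parsimony criterion,
    and each ancestral synteny graph is linearized into ordered, oriented
    contigs. Every adjacency is dated to its clade of emergence, optionally
    converted to ages in millions of years, and summarized as per-node
    phylostratigraphy. A genome-evolution simulator (inversions,
    translocations, duplications, gains, losses on a Yule tree) provides
    ground truth, and an evaluation module computes per-level precision and
    recall against it.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    data.table,
    xml2,
    jsonlite,
    rtracklayer,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
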