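Package: mirnetmapper
Title: Topology Metrics and Clustering for miRNA-mRNA Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analyzes bipartite miRNA-target interaction networks built from
    differential-expression studies. From a two-column miRNA-gene edge list
    (and an optional list of all differentially expressed genes) it computes
    the binary gene-by-miRNA adjacency matrix with per-gene degree of
    centrality, a per-miRNA impact table (fraction of all targeted genes and
    of all DE genes that each miRNA regulates), and pairwise Jaccard
    distances between miRNA target sets, which are clustered hierarchically
    to reveal groups of miRNAs acting on shared targets. Tabular, Newick and
    graphical outputs (impact barplot, dendrogram, identity heatmap) are
    produced, and a seeded generator of synthetic networks with planted hub
    genes and miRNA clusters supports validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
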