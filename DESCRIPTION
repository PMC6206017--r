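Package: metnetphylo
Title: Phylogenetic Signal from the Topology of Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds directed substrate-product metabolic networks from
    per-species reaction sets, computes per-metabolite topological metrics
    (degree, in/out-degree, clustering, HITS hub and authority scores,
    local efficiency, betweenness, eigencentrality), assembles aligned
    feature vectors over shared metabolite character sets, and infers
    dendrograms via UPGMA. Trees are evaluated against a reference
    phylogeny with the cophenetic correlation coefficient and by
    character-resampling bootstrap support. Includes a generator that
    evolves reaction repertoires along a known tree so the whole pipeline
    can be validated against a ground-truth phylogeny.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    ape,
    Matrix,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
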