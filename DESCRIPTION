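Package: herbnet
Title: Herbal Formula Discovery on Plant-Compound-Protein Networks by
    Branch and Bound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Links pharmacological networks of medicinal plants, chemical
    compounds and disease target proteins through binary-fingerprint
    Tanimoto similarity and protein identity, traverses the linked
    networks into a weighted plant-protein bipartite graph, scores
    candidate multi-plant herbal formulas by weighted protein coverage,
    and finds the top-F compositions of exactly k plants with an exact
    branch-and-bound search (breadth-first, depth-first and best-first
    strategies; binary and wide branching; lower-bound pruning) that is
    equivalent to exhaustive enumeration.  Includes seeded synthetic
    network generators, flat-file readers and writers, and an
    end-to-end pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
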