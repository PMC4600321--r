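Package: refnetq
Title: Reference-Based Indexing for Querying Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Accelerates the network query problem on large protein-protein
    interaction networks with a reference-based index. A confidence-bounded
    color-coding dynamic program aligns tree queries against an arbitrary
    weighted target with bounded node insertions and deletions. The index
    stores small random-walk reference subtrees together with their
    non-overlapping, statistically significant alignments in the target
    (permutation z-scores), reduced to a compact reference set by greedy set
    cover. Query processing screens references, composes indirect mappings,
    prunes candidates with a maximum-weight bipartite-matching upper bound,
    and finishes with a constrained induced alignment at a reduced color
    count. A synthetic instance generator (random targets, walk-sampled
    queries, topology and homology perturbation, planted motifs) supports
    end-to-end evaluation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
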