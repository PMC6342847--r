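Package: phyloflex
Title: Phylogenetic Flexibility of Taxon Coverage Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decides whether a collection of species subsets (a taxon
    coverage pattern) is phylogenetically flexible, i.e. whether every
    assignment of rooted trees to those leaf sets is compatible with a
    common supertree. Implements the thin/slim excess (Hall-type) criteria
    with brute-force and polynomial-time (submodular min-cut) deciders,
    the Aho BUILD supertree algorithm with the Bryant-Steel cluster-graph
    compatibility criterion, exhaustive flexibility testing with
    counterexample certificates, caterpillar median and lca
    representations of thin systems, and seeded generators for random set
    systems and trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
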