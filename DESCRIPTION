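Package: hubscore
Title: Rank Cancer Genes by Mutated-Interactor Network Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates per-cancer mutation tables, survival Meta-Z scores
    and a protein-protein interaction network to classify, filter and rank
    genes by a network score counting cancer-mutated interaction partners.
    Produces per-cancer ranked seed and interactor hub lists, cross-cancer
    hub intersections, min-max normalised score matrices and overlap
    statistics against external cancer-gene lists, and ships a synthetic
    cohort generator with planted hubs for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
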