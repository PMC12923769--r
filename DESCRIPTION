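Package: ecisfiber
Title: Discovery and Classification of eCIS Tail Fiber Genes and Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cataloguing tail fiber genes of extracellular
    contractile injection systems (eCIS) in bacterial and archaeal genomes.
    Implements marker-weighted detection of candidate eCIS loci from gene
    annotation tables, assignment of baseplate anchor (eBAP) domains to
    fiber gene candidates, sequence-based domain discovery with
    gradient-identity clustering and score-prioritised resolution of
    overlapping domain hits, graph-based dissection of predicted fiber
    structures into domains via secondary-structure contact graphs, domain
    co-occurrence network construction, and a taxonomic-incongruence screen
    for horizontally transferred domains. Ships deterministic synthetic-data
    generators with machine-readable ground truth so every stage is testable
    without external databases or search engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    igraph,
    bio3d,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
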