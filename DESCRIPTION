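Package: clpagnr
Title: Deterministic Community Detection by Constrained Label Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Community detection for undirected, unweighted networks with a
    fully deterministic variant of the label propagation algorithm (CLPA-GNR).
    Initial communities are seeded from mutual-neighbour scores, grown by a
    sequence of constrained label-propagation passes whose admission rules are
    gradually relaxed, refined by grouped-node reallocation, and merged under a
    modularity-guided schedule. Fixed update sequences and explicit
    tie-breaking rules remove all randomness from the detection, so repeated
    runs on the same network always return the same partition. Also bundles
    generators for the LFR, Girvan-Newman and relaxed-caveman benchmark
    families with planted ground-truth partitions, and partition-quality
    metrics (normalized variation of information, normalized mutual
    information, modularity, modularity density).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
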