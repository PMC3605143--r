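Package: svstream
Title: Linear-Time Structural-Variant Detection from Discordant Read Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A rule-based, single-pass detector of genomic structural
    variation from coordinate-mapped paired-end sequencing data. Read pairs
    are classified as normal or discordant (abnormal distance, inconsistent
    orientation, inter-chromosomal), accumulated into mergeable coarse-bin
    spatial counters, clustered into candidate features, and scored by a
    probabilistic aggregation of mapping qualities. Includes insert-size and
    read-group quality assurance, selection of comparably covered regions,
    cross-sample comparison statistics (gene disruption matrices,
    mutual-information distance, classical MDS, cluster compactness index,
    coverage-bias diagnostics, variance biclustering), and a seeded mate-pair
    simulator with planted variants so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
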