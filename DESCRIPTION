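Package: synortho
Title: Ploidy-Aware Syntenic Ortholog Networks from Collinearity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers genome-wide syntenic orthogroups across multiple species,
    including allopolyploids, by tethering sequence-similarity orthogroups
    (OrthoFinder dialect) to pairwise collinearity blocks (MCScanX dialect).
    Orthogroups whose per-species tandem-aware gene-set counts are within the
    expected relative ploidy become "tethers"; every gene pair of every
    collinear block is scored Pass / Not Pass / No Call against the tethers;
    blocks are filtered, end-trimmed and split by a fixed set of decision
    rules; and the surviving gene pairs, together with tandem-duplicate
    edges, are assembled into an undirected graph whose connected components
    are the final orthogroups. Includes readers and writers for the external
    file dialects, a gene-name translation utility for GFF3 and protein
    FASTA inputs, and a synthetic multi-genome simulator with planted ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
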