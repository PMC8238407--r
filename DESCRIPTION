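Package: txconcord
Title: Multi-Platform Transcriptome Detection Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Compare gene detection across transcriptome profiling platforms
    (short-read RNA-seq, long-read nanopore sequencing, qPCR panels) against a
    declared gene universe. Provides cutoff-ladder detection calls, Tanimoto
    (Jaccard) set similarity with interpretation bands, k-way Venn
    partitioning, platform-count reliability tiers, platform-unique and
    undetected gene accounting, genome-coverage fractions, replicate-batch
    concordance, deterministic JSON/TSV reporting, and a seeded synthetic
    multi-platform expression generator with per-gene ground truth for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
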