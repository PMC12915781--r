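Package: tamscan
Title: Transcription-Associated Mutation Enrichment in Genomic Windows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether spontaneous mutations accumulate preferentially in
    highly transcribed genomic regions. Quantifies expression depth (TPM) and
    breadth (percent of bases covered) in sliding genomic windows from per-base
    RNA-seq coverage tracks, overlaps mutation calls with windows and genes,
    and assesses enrichment with one-sided median permutation tests, including
    GC-matched controls, expression-quartile enrichment, a multi-profile test
    battery, and an exhaustive small-instance oracle. Ships a synthetic-data
    generator with a tunable expression-to-mutation effect size so every stage
    of the pipeline can be verified end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    methods,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
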