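Package: virtukaryo
Title: Virtual Karyotyping of Soft-Masked Genome Assemblies and Trout Cytotaxonomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed composition analysis of soft-masked chromosome-level
    genome assemblies: repeat proportion and GC content of the repetitive and
    non-repetitive fractions in non-overlapping windows, assembled into
    size-sorted "virtual karyotype" plots with annotation overlays. Also
    provides group-wise genome-size versus GC content trend comparison for
    genome-record tables, karyotype arithmetic (diploid number 2n and the
    fundamental number NF, the chromosome-arm count) with a curated review
    table of brown trout (genus Salmo) karyotypes, and seeded generators of
    synthetic soft-masked genomes and trend tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    rlang,
    tibble,
    dplyr,
    readr,
    ggplot2,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
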