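Package: orthomethr
Title: Cross-Species Comparison of Promoter DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing promoter DNA methylation between species
    measured with CpG-unit-resolution bisulfite assays (MassARRAY/EpiTYPER
    style data). Implements orthologous promoter-region design from
    alignment hit tables (hit-count filtering, overlap merging, length
    filtering, symmetric extension), orthologous CpG-site and CpG-unit
    pairing on bisulfite-converted pairwise alignments, NA-tolerant
    region- and unit-level differential-methylation calling with an
    effect-size plus FDR criterion, CpG observed/expected density
    profiling against methylation and expression, phylogenetic
    classification of lineage-specific methylation gains and losses, and
    a seeded synthetic-data generator producing paired-species promoter
    sequences, unit-level methylation tables and coupled expression
    values for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
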