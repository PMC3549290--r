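Package: cisnat
Title: Detection and Small RNA Profiling of Cis-Natural Antisense Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying cis-natural antisense transcript (cis-NAT)
    pairs from strand-resolved transcript models, classifying their overlap
    orientation (enclosed, convergent, divergent) and partner biotypes,
    grouping pairs into sense-antisense networks, assigning nat-siRNAs from
    mapped small-RNA libraries to overlap regions with strand-bias, density
    and exclusivity statistics, and calling per-condition expression,
    sense/antisense ratio subgroups and Fisher-exact differential expression
    on count libraries. Includes a seeded synthetic-data generator that
    plants ground-truth pair, network, small-RNA and expression structure so
    the whole pipeline runs and is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    igraph,
    generics,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    BiocGenerics,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
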