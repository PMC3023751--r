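Package: radmap
Title: RAD-Seq SNP Discovery, Doubled-Haploid Linkage Mapping and QTL Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for restriction-site associated DNA
    (RAD) genotyping-by-sequencing in biparental doubled-haploid populations.
    Demultiplexes 36-nt single-end reads by inline barcode and restriction
    remnant, collapses 28-nt sequence tags into depth-filtered clusters,
    discovers codominant SNP markers by cross-parent k-mer matching, calls
    genotypes with a strict conflict rule, applies marker and line quality
    control (missing-data filter, duplicate-line detection, segregation
    distortion, singleton recoding), builds a genetic map by two-point LOD
    grouping with Haldane distances and SARF/2-opt ordering, and maps
    quantitative trait loci by composite interval mapping with stepwise
    cofactor selection and permutation thresholds. Includes a ground-truthed
    simulator of RAD experiments for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    generics,
    ggplot2,
    igraph,
    withr,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
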