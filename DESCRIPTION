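Package: triophase
Title: Trio Binning of F1 Hybrid Long Reads with Concordance and
    Windowed p-Distance Quality Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Haplotype phasing of F1 interspecies hybrid long reads by
    parent-specific k-mer markers derived from parental short reads (trio
    binning), together with two quality-control procedures: a phased
    haplotype analysis (PHA) that quantifies concordance between a
    reference-cross and a replacement-cross binning of the same reads,
    and a windowed uncorrected p-distance track over reference-coordinate
    consensus sequences with detection of in-group/out-group separation
    flips. A fully seeded synthetic trio generator (parental genomes at a
    target divergence, within-species replacement individuals, long and
    paired short reads with truth labels) provides desk-scale inputs so
    the whole pipeline runs without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
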