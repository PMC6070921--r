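Package: arvprofiler
Title: Targeted DNA/RNA Profiling of Androgen Receptor Aberrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies androgen receptor (AR) splice-variant fractions from
    exon-exon junction signature sequences, estimates AR copy number from
    windowed targeted-panel coverage, calls structural rearrangements from
    split reads, calls hotspot point mutations from pileups, and scores AR
    signalling as a summed z-score of androgen-responsive genes. Ships a
    synthetic targeted-sequencing data generator with known truth so the
    whole pipeline is testable end to end, plus cohort-level summaries
    (Mann-Whitney group comparisons, Spearman correlations, alteration
    frequency tables).
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
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
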