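Package: sniperkit
Title: High-Throughput CRISPR-Cas9 Guide Activity, Specificity and
    DNA-Unwinding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative machinery for characterizing high-fidelity
    SpCas9 variants from paired sgRNA-target library screens:
    background-corrected indel frequency estimation from amplicon
    sequencing with read-count and background filtering, PAM
    compatibility and mismatch-tolerance analytics, activity-specificity
    trade-off summaries, convolutional sequence-to-activity regression
    networks for on- and off-target activity prediction, and
    single-molecule FRET two-state population analysis of DNA unwinding.
    Includes a synthetic-data module that generates library designs,
    ground-truth activity landscapes, simulated amplicon reads and
    simulated fluorescence traces so that every stage of the pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    Biostrings,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
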