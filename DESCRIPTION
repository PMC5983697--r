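Package: tfscreen
Title: Integrative Screening of Transcription-Factor Target Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrates chromatin immunoprecipitation sequencing (ChIP-seq)
    peak locations, perturbation expression contrasts (overexpression and
    knockdown), and tumor-cohort co-expression to prioritize direct
    transcriptional targets of a regulator. Pools peak sets into loci,
    assigns each locus to the nearest transcription start site with a
    signed distance, summarizes the promoter-window distance distribution,
    computes fold-change ratios and cross-dataset concordance, screens
    cohort-wide correlation with the regulator, applies a disjunctive
    candidate-selection rule, and evaluates candidates by
    median-bifurcation survival analysis (Kaplan-Meier, log-rank,
    observed-over-expected hazard ratio). Ships a seeded synthetic-data
    generator with a planted-truth manifest so the whole pipeline is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    survival,
    GenomicRanges,
    IRanges,
    rtracklayer
Config/testthat/edition: 3
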