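Package: kmerscreen
Title: K-mer Subtraction Screening for Tumor-Specific Antisense Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tumor-versus-normal transcriptome subtraction built on 25-mer
    catalogs: per-sample k-mer counting with an occurrence threshold,
    count-per-billion-bp normalization with asymmetric imputation,
    per-tissue minimum-tumor to maximum-normal abundance ratios, transcript
    ranking by over-abundance breadth, and antisense target selection.
    Companion viability-plate analytics cover fraction-dead computation,
    linear sensitivity and slope-derived EC50, median-effect (mass-action)
    dose-response fitting, and Chou-Talalay combination-index synergy
    classification. Includes a seed-deterministic synthetic cohort and
    viability-plate simulator so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
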