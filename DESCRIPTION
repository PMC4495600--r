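Package: sumovar
Title: Prediction of Lysine Sumoylation Sites and Classification of
    Sumoylation-Related Amino Acid Variants
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts lysine sumoylation sites from protein sequences using
    windowed sequence, structure and evolutionary-profile encodings, F-score
    feature ranking with forward wrapper selection, and an ensemble of
    balanced-negative radial-basis-kernel soft-margin classifiers with
    specificity-calibrated probability thresholds.  Classifies amino acid
    substitutions by their effect on sumoylation (site creation or removal at
    the mutated residue, gain or loss at neighbouring lysines, or alteration
    of the recognition context of a site that stays modified), and provides
    contingency-table tests, two-sample-logo enrichment, motif extraction,
    and a synthetic proteome/variant generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
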