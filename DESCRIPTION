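Package: prmquant
Title: Absolute Protein Quantitation from Targeted Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("PRM", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for absolute protein quantitation from
    targeted mass spectrometry (PRM/SRM) transition-level peak areas using
    stable-isotope dilution with heavy-labeled peptide standards. Computes
    light/heavy ratios over common transitions, estimates and corrects
    heavy-standard bleed-through from blank runs, applies rule-based
    quantitation quality classification, aggregates replicates by geometric
    means to protein copies per cell, selects quantotypic tryptic peptides
    in silico, and extends measured abundances proteome-wide through a
    log-log regression of protein copies per cell on transcript abundance
    (TPM). Includes a ground-truthed synthetic data generator so that every
    stage of the pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    jsonlite
Config/testthat/edition: 3
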