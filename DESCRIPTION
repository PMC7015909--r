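Package: prmkinome
Title: SILAC Parallel Reaction Monitoring Kinome Quantification and Survival Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a SILAC parallel-reaction-monitoring
    (PRM) targeted proteomics workflow for kinome-wide protein quantification:
    peptide and y-ion monoisotopic mass arithmetic for light/heavy SILAC
    channels, a Skyline-style spectral-library data model, extracted-ion
    chromatogram peak detection and integration, spectral-library dot-product
    (dotp) and co-elution quality gates, light/heavy peptide ratio estimation,
    label-swap (forward/reverse) reconciliation into protein-level fold
    changes with RSD-based regulation calls, kinome summary matrices, and a
    quartile-stratified Kaplan-Meier/logrank survival screen. A synthetic
    chromatogram generator with known ground truth stands in for instrument
    raw data so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
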