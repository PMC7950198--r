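Package: agpglyco
Title: Site-Specific N-Glycosylation Profiling of Alpha-1-Acid Glycoprotein
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Targeted, site-specific quantification of alpha-1-acid glycoprotein
    (AGP) N-glycopeptides from LC-MS1 data. Builds a tryptic glycopeptide analyte
    library for the AGP1 (F1/F2/S) and AGP2 protein variants with theoretical
    isotopic envelopes, performs retention-time alignment and targeted
    isotopologue integration with mass-accuracy, isotopic-pattern and
    signal-to-noise quality metrics, curates and normalizes glycoform abundances
    per glycosylation site, computes derived glycosylation traits (branching,
    fucosylation, sialylation ratio), and runs stability (coefficient of
    variation) and case/control association analyses with empirical-Bayes batch
    correction, rank-based inverse normal transformation, Benjamini-Hochberg
    false discovery rate control and ROC model comparison. Includes simulators
    for raw runs, cohorts and longitudinal stability designs so every stage can
    be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    sva
Suggests:
    testthat (>= 3.0.0),
    mzR,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
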