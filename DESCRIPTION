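Package: evanomaly
Title: Anomaly Detection for Small-Cohort Protein Abundance Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Detects "extremely changing" proteins in label-free
    quantification peak-area tables from small donor cohorts (three donors
    in the motivating extracellular-vesicle proteomics study). Each protein
    is a point in donor space whose coordinates are its log abundances in
    the D donors; the pipeline log-transforms the peak areas, retains the
    primary OPTICS density cluster, scores points per condition with an
    isolation forest, and thresholds the per-protein cross-condition
    Euclidean displacement at the mean plus k standard deviations. A
    descriptive layer adds per-protein t-test tiers, log fold change,
    within-group variance and coefficient of variation, a quadratic fold
    change versus distance fit, and Venn region counts. A synthetic-data
    generator with planted anomalies, donor effects and a low-abundance
    contaminant cloud makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
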