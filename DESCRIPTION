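Package: myopheno
Title: Quantitative Muscle MRI, Biomechanics and Histopathology Pipeline
    for Preclinical Muscular Dystrophy Trials
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable analysis pipeline for preclinical canine muscular
    dystrophy (GRMD) trial data: per-voxel T2 mapping from multi-echo
    spin-echo MRI, per-muscle 3D gray-level run-length texture biomarkers
    (Small Lesion Index / short run emphasis, Heterogeneity Index /
    run-length non-uniformity, histogram entropy) with proportional
    volume-weighted composites, biomechanical endpoint reduction
    (torque-to-force conversion, body-mass correction, eccentric
    contraction force deficit), a histopathology percent-rescue composite
    score, and a Welch t-test plus Benjamini-Hochberg FDR group-comparison
    layer. Includes a seeded synthetic-data generator (multi-echo phantoms
    with patchy hyperintense lesions, cohort tables, histology marker
    counts) so the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
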