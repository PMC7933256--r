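Package: atriamorph
Title: Left Atrial Shape Quantification from Triangulated Surface Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies left atrial (LA) shape from closed triangulated
    surface meshes segmented from cardiac CT. Provides closed-mesh volumetry
    and plane clipping (total, anterior and posterior LA volumes and the
    asymmetry index ASI = LA-A/LAV), a patient-specific best-fit sphere via
    iterative closest point registration, signed radial deviation mapping
    with automatic exclusion of protruding structures (pulmonary veins, LA
    appendage) and the sphericity index LAS = 1 - S/AR, a landmark-driven
    six-segment regional partition with segmental wall deviation D, a
    nonparametric statistical battery relating shape metrics to per-segment
    low-voltage labels, and a synthetic-atrium cohort generator with
    analytic ground truth so that every stage is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, jsonlite
Suggests: testthat (>= 3.0.0), withr, yaml, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
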