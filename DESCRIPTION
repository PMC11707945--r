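Package: gajunct
Title: Junctional-Zone Microperimetry Analysis for Geographic Atrophy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing microperimetry (MP) sensitivity in the
    junctional zone of geographic atrophy (GA) lesions. Registers MP
    stimulus coordinates into the fundus-autofluorescence (FAF) frame via
    fiducial-based similarity transforms, computes signed Euclidean
    distances from each stimulus to traced GA lesion margins, derives
    zone-restricted visual-function metrics (mean sensitivity, scotomatous
    point counts), and quantifies inter-grader repeatability with
    Bland-Altman limits of agreement, intraclass correlation coefficients
    and coefficients of repeatability, including a repeated-measures
    variant based on variance components. A synthetic-study generator
    (multifocal lesion polygons, distance-dependent sensitivity fields,
    grader fiducial jitter, 4-2 staircase measurement) provides fully
    reproducible data with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
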