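Package: microtese
Title: Surface-Area Maximization Geometry and Cohort Statistics for
    Microdissection Testicular Sperm Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the testis as an ellipsoid with integer semi-axis ratios
    and computes the exposed, searchable cut-surface area produced by every
    feasible combination of tunical incision (longitudinal or transverse) and
    serial parenchymal slicing plane (transverse, sagittal or coronal) in
    microdissection testicular sperm extraction (microTESE). Closed-form
    cross-section and slice-face-sum formulas are verified against direct
    summation and an independent numeric quadrature oracle, and the four
    feasible strategies are ranked; a longitudinal tunical incision with
    transverse slices maximizes the searchable area for any strictly ordered
    ellipsoid. Also includes the accompanying clinical biostatistics:
    sperm-retrieval-rate tables, uncorrected Pearson chi-square comparison
    of two surgical cohorts with etiology and histopathology subgroups, a
    seeded synthetic Bernoulli cohort generator, and Monte-Carlo power and
    type-I-error calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
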