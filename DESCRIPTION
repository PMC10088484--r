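Package: roilsm
Title: Region-Based Lesion-Symptom Mapping and Lesion-Based Prediction of
    Aphasia Severity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for relating focal brain damage to behavioural impairment
    at the level of atlas-defined regions of interest. Reads binary lesion
    masks and labelled parcellations in NIfTI-1 format, quantifies the
    fraction of each region destroyed by a lesion, and builds cohort-level
    damage matrices. Provides region-based lesion-symptom mapping with
    max-statistic permutation family-wise error correction, linear
    support-vector-regression models predicting severity scores from regional
    damage or from lesion volume alone (leave-one-out and cross-cohort
    designs), Fisher r-to-z comparison of prediction accuracies, dice overlap
    of significant region sets, and a synthetic stroke-cohort generator with
    a known ground-truth damage-to-severity law so that every stage of the
    pipeline can be validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
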