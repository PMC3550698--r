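Package: spectscore
Title: Automated Polar-Map Scoring and Prognostic Analysis of Myocardial SPECT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies short-axis myocardial SPECT count volumes (stress/rest
    thallium-201 and rest BMIPP) into percent-uptake polar maps, partitions them
    into the standard 17-segment left-ventricular model, scores each segment from
    0 (normal) to 4 (absent uptake) against a configurable threshold table and
    normal database, and computes summed scores (SSS, SRS, SDS, SBS) with the
    >= 4 abnormality cutoff. Includes the accompanying prognostic toolkit
    (contingency tables and predictive values with AND/OR score combination,
    Kaplan-Meier curves, log-rank tests, Cox proportional-hazards fits with
    global chi-square increments, ROC AUC with DeLong comparison, baseline
    tables) and synthetic generators for left-ventricular phantom volumes with
    configurable perfusion defects and for survival cohorts with
    proportional-hazards structure, so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    survival,
    pROC,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
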