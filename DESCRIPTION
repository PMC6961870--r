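Package: csftriage
Title: Decision Support for CSF Biomarker Triage in Differential
    Dementia Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Multi-class Disease State Index (DSI) classification of
    memory-clinic patients (controls, Alzheimer's disease, frontotemporal
    dementia, vascular dementia) from neuropsychology, MRI markers, APOE
    and CSF biomarkers; personalized classification confidence via the
    probability of correct class (PCC); and a stepwise scenario engine
    that simulates AD-like and normal CSF biomarker profiles to decide
    for which patients actual CSF testing is worth ordering.  Includes a
    seeded synthetic four-group cohort generator, calibration and
    cutoff-sweep diagnostics, scenario summary statistics and plain-text
    patient reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
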