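Package: cstflow
Title: Cortico-Striatal-Thalamic Circuit Mapping from Arterial Spin
    Labeling Perfusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Atlas-based analysis of arterial spin labeling (ASL) cerebral
    blood flow (CBF) images over cortico-striatal-thalamic (C-S-T)
    functional circuits. Builds the six-subdivision compartment taxonomy
    from striatal, thalamic and cortical label volumes, extracts absolute
    and whole-cortex-ratio CBF per compartment, compares a single patient
    examination against a matched normative cohort with a single-case
    (Crawford-Howell) t-test, detects coincident circuit-level changes,
    summarises groups with exact contrasts, and renders donut-chart
    reports. A companion electrophysiology module performs jerk-locked
    back-averaging of EEG on EMG jerk onsets and summarises inter-discharge
    intervals of periodic discharges. A synthetic-data module generates
    fixture atlases, age-structured control cohorts, patient examinations
    with injected circuit effects, and polygraphic EEG/EMG recordings with
    periodic complexes, with full ground-truth bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    ggplot2,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
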