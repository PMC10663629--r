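Package: pupildoc
Title: Pupillometry and ERP Markers of Consciousness in the Auditory
    Local-Global Paradigm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to generate auditory local-global oddball stimulus
    schedules, preprocess bedside pupillometry and high-density EEG
    recordings with explicit artifact-rejection rules, compute sample-wise
    pupil-dilation-response (PDR) and event-related-potential (ERP) effect
    statistics with false-discovery-rate control, and evaluate the
    diagnostic and prognostic performance of these markers in patients with
    disorders of consciousness. Includes a synthetic-data module that
    simulates pupil traces (dilation kernel, blinks, autocorrelated noise),
    multichannel EEG epochs (MMN- and P3b-like components), and patient
    cohorts, so every pipeline stage is testable without clinical
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
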