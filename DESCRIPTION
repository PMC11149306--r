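Package: ftcp
Title: Frequency-Tagging EEG and Behavioral Measures of Categorical Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement chain for sweep frequency-tagging oddball EEG and
    behavioral assessment of categorical perception. Encodes the experimental
    design (7-step sweep trials at a 6 Hz base / 1.2 Hz oddball rate,
    same-different discrimination, 3-block category training) as data,
    simulates multichannel EEG recordings and signal-detection/learning
    observers with the assumed statistical structure, quantifies oddball
    responses from amplitude spectra (surrounding-bin baseline correction,
    z-scored harmonic significance, harmonic summation, region-of-interest
    selection), and analyses behavior (d-prime per pair type, categorical
    perception contrast, logistic psychometric fits of the category boundary,
    variance-ratio and correlation tests). An orchestration layer runs
    simulate-quantify-analyse pipelines and assembles tidy contrast tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
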