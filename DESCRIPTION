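Package: pupilmem
Title: Single-Trial Pupillometry Analysis of Subsequent Memory Recall
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying the subsequent memory effect in auditory free
    recall with pupillometry. Cleans raw pupil-diameter traces (sliding-window
    blink detection, padded removal, linear interpolation, trial and
    participant validity filtering), extracts baseline-corrected peak pupil
    dilation (PPD) per sentence, and models word-level recall with a binary
    logistic mixed model with crossed random intercepts for participant and
    serial position, fit by Laplace-approximated maximum likelihood. Includes
    Type-II Wald tests, likelihood-ratio tests, variance inflation factors,
    Nakagawa marginal and conditional R-squared, repeated-measures power
    analysis via the noncentral F distribution, and a synthetic-study
    generator with known ground truth for end-to-end parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    Matrix,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    car,
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
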