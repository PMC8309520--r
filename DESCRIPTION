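Package: pupilrhythm
Title: Non-Contact Motion-Sickness Measurement from Pupillary Rhythms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for measuring motion sickness from infrared eye
    images without body-contact sensors. Segments the pupil in IR
    frames with auto-threshold binarization, glint anchoring and
    Daugman-style circular edge detection; resamples the 30 fps
    diameter signal into a 1 Hz pupillary rhythm; computes the three
    sickness indicators (mean and standard deviation of the rhythm and
    the pupillary rhythm coherence ratio); scores the 16-item
    Simulator Sickness Questionnaire; trains and evaluates LDA,
    decision-tree and SVM classifiers with stratified cross-validation;
    and reproduces the study-level statistics (paired t-tests with
    Cohen's d, baseline-covariate ANCOVA with partial eta-squared,
    partial correlations, Bonferroni correction). A synthetic-data
    module generates ground-truth eye frames, diameter traces, SSQ
    responses and labeled cohorts so the full pipeline is testable
    without recorded data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    png,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    zoo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
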