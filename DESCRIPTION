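Package: qeegicp
Title: Quantitative EEG Prediction of Increased Intracranial Pressure
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for predicting increased
    intracranial pressure (ICP >= 25 mmHg) from single-channel quantitative
    EEG recorded during a stepwise intracranial balloon-inflation injury
    protocol. Provides a synthetic cohort generator with ICP-dependent
    spectral profiles, zero-phase band-pass filtering and overlapping epoch
    segmentation, a bank of time-, frequency- and entropy-domain qEEG
    features, neighborhood component analysis feature ranking with t-test
    filtering, four classifier configurations (logistic regression, kernel
    naive Bayes, Gaussian-kernel support vector machine, random-subspace
    tree ensemble), and subject-split evaluation with cluster-bootstrap
    confidence intervals.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    rpart,
    signal,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
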