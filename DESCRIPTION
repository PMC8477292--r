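Package: hvec
Title: Hierarchical Visit Embeddings for Imbalanced Clinical Outcome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts 30-day mortality and readmission from longitudinal
    claims sequences with a hierarchical vectorizer: per-record code-embedding
    summation into a fixed-layout feature vector, a fully-connected record
    encoder feeding a recurrent (LSTM) person state, and one prediction head
    per main and auxiliary task. Training combines auxiliary-task gradients
    with the main-task gradient through a cosine gate, and counters extreme
    class imbalance (cardiac-arrest outcome rates near 0.5%) with person-level
    upsampling and record-level loss weighting. Includes a synthetic claims
    cohort generator with a planted severity signal, 30-day outcome labeling
    with anti-leakage rules, person-level splitting, and AUROC/F1 evaluation
    on ALL-record and cardiac-arrest record subsets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    pROC
Config/testthat/edition: 3
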