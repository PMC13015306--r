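Package: breathdecode
Title: Respiration Cycle Features and Single-Trial Decoding of Behavioral Outcome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking breathing to trial-by-trial behavior in task-based
    physiology experiments. Conditions a continuous respiration recording
    (narrowband Butterworth filtering, inversion, z-scoring), segments it into
    breath cycles by peak/valley detection with prominences, extracts a canonical
    set of twelve trial-aligned cycle features (timing, depth, volume, Hilbert
    phase), compares features by trial outcome with session-level and
    within-session tests, and decodes single-trial outcome with a small model zoo
    under five-fold and leave-one-session-out cross-validation, including feature
    importance and exhaustive feature-subset sweeps. A synthetic-data module
    generates respiration recordings and trial tables with known planted
    outcome-dependent effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    class,
    e1071,
    jsonlite,
    nnet,
    pROC,
    pracma,
    randomForest,
    signal,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
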