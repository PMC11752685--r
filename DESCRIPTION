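Package: cholmech
Title: Mechanistic Cholestasis Prediction by Transporter QSAR and Reverse Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts drug-induced cholestasis with a mechanistic pipeline:
    per-hepatic-transporter IC50 QSAR models (random forest, support vector
    machine, gradient boosting over an eight-transporter panel), a
    six-compartment flow-limited physiologically based toxicokinetic (PBTK)
    model of repeated oral dosing, quantitative in vitro-in vivo
    extrapolation (QIVIVE) reverse dosimetry from inhibitory concentration to
    oral-equivalent dose, and rule-based classification of compounds by
    comparing therapeutic dose against the extrapolated transporter-inhibiting
    doses. Includes synthetic-data generators for fully offline testing, a
    compound-table reader for the seven-column tabular schema, evaluation
    metrics (sensitivity, specificity, accuracy, MCC, AUC) and a command-line
    entry point.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    deSolve,
    randomForest,
    e1071,
    xgboost,
    readxl,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
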