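Package: mindwandr
Title: Mind-Wandering Detection from ERP Features in Oddball-Task EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for EEG-based detection of
    mind wandering during an auditory oddball (target detection) task.
    Generates synthetic epoched EEG sessions with thought-probe labels and
    attention-state-dependent N1/P3 components, extracts block-level ERP
    features (peak mean and variability over pre-probe trials), balances
    classes with SMOTE, and evaluates person-dependent (5-fold) and
    person-independent (leave-one-subject-out) classifiers (RBF-kernel SVM
    and logistic regression) with accuracy, AUC, MCC and confusion
    matrices, plus univariate 2x2 attention-by-tone ANOVA and paired
    t-tests on ERP peak amplitudes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
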