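Package: srseeg
Title: Epileptic EEG Classification with Random-Sampling Features and a
    Least-Squares SVM
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies single-channel EEG records as healthy or ictal
    (seizure) using a three-stage pipeline: hierarchical simple random
    sampling of each record with finite-population-corrected (Cochran)
    sample sizes, nine descriptive statistics per subsample as features,
    a threshold-style sequential feature selection on per-column
    summaries, and a binary least-squares support vector machine with a
    radial-basis-function kernel trained by solving one dense linear
    system.  Includes a reader and writer for the Bonn-style one-integer-
    per-line ASCII record format, a synthetic two-class EEG generator for
    testing, stratified train/test splitting, and accuracy, sensitivity
    and specificity reporting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
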