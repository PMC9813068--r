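Package: depthfusion
Title: Cooperative AI-Endoscopist Diagnosis of Early Gastric Cancer Invasion Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for combining a probabilistic classifier with an expert
    panel's majority vote to call the invasion depth of early gastric cancer
    (intramucosal M versus submucosal SM). Implements confidence
    stratification of classifier probabilities and of panel votes, a
    confidence-aware decision-fusion table with four mismatch-resolution
    patterns selected by F1 on training data, enumeration of rater subsets
    for majority voting, a leave-one-out evaluation harness generic over a
    pluggable classifier, the full set of diagnostic-accuracy statistics
    (sensitivity, specificity, PPV, NPV, F1) with reconstruction of
    confusion counts from printed operating points, and a calibrated
    synthetic cohort generator with correlated rater votes for end-to-end
    testing without access to the original images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
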