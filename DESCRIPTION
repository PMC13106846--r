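Package: ecgcomplexity
Title: Non-Linear Complexity Analysis of Normal-Sinus-Rhythm ECGs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting subjects prone to exercising ectopic beats
    from resting or low-intensity-exercise single-lead electrocardiograms in
    normal sinus rhythm. Provides automated extraction of artefact-free 60-s
    strips in a stable heart-rate band, symbolic coarse-graining of the ECG
    waveform (threshold-crossing and fiducial-marker feature-detection
    schemes), six disorderliness estimators (Lempel-Ziv '76 and '78,
    Titchener T-complexity, Shannon entropy, approximate and sample entropy),
    polynomial heart-rate correction of complexity values with AIC model
    selection, per-beat restitution intervals (RR, QT, TQ, QRS width) with a
    triplet k-nearest-neighbour classifier, and diagnostic evaluation
    (Welch t-tests, ROC/AUC, sensitivity/specificity with Wald intervals,
    clinical utility indices). A parameterised synthetic single-lead ECG
    generator with exact ground-truth fiducials makes the whole pipeline
    testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    pROC
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
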