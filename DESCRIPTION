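Package: aneuhemo
Title: Hemodynamic Wall Shear Stress Descriptors and Matched-Pair Rupture
    Risk Scoring for Intracranial Aneurysms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the seven wall-shear-stress (WSS) derived hemodynamic
    descriptors used in intracranial-aneurysm rupture research (time-averaged
    WSS, normalized WSS, WSS spatial gradient, oscillatory shear index,
    relative residence time, combined hemodynamic parameter, and low shear
    area) from time-resolved WSS vector fields on triangulated aneurysm
    surface meshes; fits matched-pair (1:1 conditional) univariate and
    stepwise-forward multivariate logistic regression from the conditional
    likelihood; and builds and evaluates an integer-point predictive rupture
    score with ROC/Youden cutoffs and DeLong AUC comparison. A synthetic
    phantom and cohort module generates pulsatile WSS fields with known
    ground-truth descriptors and matched case-control cohorts with specified
    log-odds effects, so every stage is testable without patient CFD data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    pROC,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
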