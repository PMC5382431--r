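Package: ribdose
Title: Dosimetric Prediction of Rib Fracture After Stereotactic Ablative
    Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for dose-volume analysis of radiation-induced rib fracture
    after stereotactic ablative radiotherapy (SABR) of lung tumors.  Converts
    physical dose grids to 2-Gy equivalent dose (EQD2) under the
    linear-quadratic model, computes cumulative absolute-volume dose-volume
    histograms (DVH) for rib structures and the D_V / V_D metric families,
    selects the most predictive metric and its cutoff by ROC analysis
    (Mann-Whitney AUC, Youden index), models time-to-fracture with
    Kaplan-Meier, log-rank and Cox proportional-hazards methods, and emulates
    10-phase respiratory dose accumulation to compare 3D planning dose with
    4D cumulative dose.  A seeded synthetic cohort generator reproduces the
    statistical structure of a SABR lung cohort so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
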