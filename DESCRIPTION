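Package: laflow
Title: Left Atrial Acceleration Factor from 4D Flow MRI as a Correlate of
    Wedge Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and statistical evaluation of the left atrial (LA)
    acceleration factor, a dimensionless ratio of the early diastolic LA peak
    outflow velocity to the average of the systolic and early diastolic LA
    peak inflow velocities, as a non-invasive estimator of mean pulmonary
    artery wedge pressure (PAWP) in pulmonary hypertension. Provides a
    calibrated synthetic-cohort generator (three-group truncated-normal PAWP
    mixture, group-conditional pulmonary venous and transmitral peak
    velocities, velocity-time waveforms and toy 4D velocity fields), peak
    velocity extraction at junction, valve-tip and intra-vein measurement
    locations, the general outflow/inflow velocity-ratio family with
    non-linear least-squares model selection and large-sample confidence
    intervals, linear calibration with PRESS cross-validation, inverted
    regression with Bland-Altman agreement, ROC analysis with
    regression-derived and Youden cut-offs, and the supporting group
    comparisons, partial F-tests, one-sample t-tests and Williams-Hotelling
    comparisons of dependent correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
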