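Package: hybridreach
Title: Simulation and Analysis of Hybrid Trans-Humeral Prosthesis Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale emulation of goal-directed pick-and-place reaching
    with a seven-degree-of-freedom virtual arm under natural and hybrid
    (shoulder-driven, distal-joints-predicted) control. Provides the arm
    kinematic model (forward kinematics, joint-angle extraction, damped
    least-squares inverse kinematics), a gridded target task environment
    with trial lifecycle logic, a synthetic subject that generates
    naturalistic reaching recordings and closed-loop compensatory behaviour,
    multilayer-perceptron regressors that predict four distal joint angles
    from shoulder kinematics with or without target context, and the
    evaluation machinery: offline prediction RMSE, approach time and speed,
    shoulder-spread ellipsoid volume, reaching-posture variability, PCA
    postural synergies with principal-angle subspace distances, and a
    condition-comparison statistical report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    signal,
    car,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
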