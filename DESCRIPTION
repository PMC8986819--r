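Package: relaxstab
Title: Stability Analysis of Multiexponential Relaxometry Parameter Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the stability of parameter estimation from
    one-, two-, and three-dimensional multiexponential magnetic resonance
    relaxometry decay data. Provides noise-free forward evaluation of
    multicomponent T2, T1-T2, and T1-T2-ADC signal models with analytic
    Jacobians, linearized (Cramer-Rao type) parameter covariance and Jacobian
    condition-number calculations, Monte-Carlo simulation of noisy
    acquisitions with nonlinear least-squares recovery, parameter-sweep
    pipelines comparing the conditioning of 1D, 2D, and 3D experiments, and a
    synthetic emulation of a two-gel phantom relaxometry study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
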