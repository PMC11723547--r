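Package: pwfrac
Title: Piecewise Fractional and Stochastic Simulation of Cancer Progression
    Dynamics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@pwfrac.org",
           role = c("aut", "cre"))
Description: Simulates a five-compartment model of breast cancer progression
    and chemotherapy-induced cardiotoxicity under a piecewise differential
    operator: a constant-order Caputo-proportional-constant (CPC) fractional
    operator on the first time interval, a variable-order CPC operator on the
    second, and a stochastic system driven by fractional Brownian motion on
    the third.  Fractional regimes are integrated with a Grunwald-Letnikov
    nonstandard finite-difference scheme over the full solution history;
    the stochastic regime uses an Euler-Maruyama scheme with a Hurst-index
    correction term.  Includes generators for the Grunwald-Letnikov weight
    sequences, an exact-covariance fractional Gaussian noise generator
    (circulant embedding), analytic certificates (Lipschitz matrix,
    contraction factor, stochastic Lyapunov bound), scenario presets,
    parameter sweeps and reference-fixture generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    deSolve
Config/testthat/edition: 3
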