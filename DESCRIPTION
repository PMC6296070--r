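Package: gutswitch
Title: Bistable Dynamics of Gut Inflammation and Butyrate
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Qualitative dynamical model of the interplay between the
    NF-kB inflammatory signalling system of gut epithelial cells and
    microbially derived butyrate, with lipopolysaccharide (LPS) influx
    through a leaky barrier. Provides the core and extended ODE systems
    with analytic Jacobians, stiff time integration under piecewise
    constant lumen-butyrate pulse protocols, multistart Newton
    equilibrium location with linear stability analysis, pseudo-arclength
    continuation with saddle-node (fold) detection and quadratic
    normal-form coefficients, invariant-box and positive-orthant
    verification, and the change-of-variables transform that maps a
    Gaussian lumen-butyrate distribution through the hysteresis into a
    bimodal within-cell butyrate distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
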