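Package: pinnode
Title: Physics-Informed Neural Networks for Systems of Ordinary
    Differential Equations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward and inverse problems for systems of first-order
    ordinary differential equations solved with physics-informed neural
    networks (PINNs). A tanh feedforward network approximates the solution
    while a composite loss (data misfit, initial-condition misfit, and the
    squared ODE residual at collocation points, combined with equal weights)
    is minimized with Adam; for the inverse problem the ODE parameters are
    estimated jointly with the network weights. Includes two
    systems-biology case studies (logistic population growth and
    promoter/transcription-factor binding kinetics), a synthetic-data
    generator, a plain neural-network baseline for comparison, and a
    command-line interface. The network forward pass, its exact input
    derivative (forward-mode differentiation), and all gradients are
    implemented in the package, with a compiled (RcppArmadillo) training
    loop for the built-in systems and a plain R reference loop for
    user-defined ones.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
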