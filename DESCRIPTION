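Package: nodefit
Title: Fitting ODE and Neural-ODE Models to Oscillatory Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fitting ordinary differential equation (ODE) and
    neural-ODE (NODE) models to noisy oscillatory time series such as
    predator-prey abundance records. Provides data smoothing (log transform,
    mean-centering, cubic-spline midpoint interpolation, Gaussian filtering),
    trajectory solving with stiff integrators and exact gradients via forward
    sensitivity analysis, Adam optimization with a sequential ramped-weight
    curriculum, preconditioned stochastic gradient Langevin dynamics (pSGLD)
    posterior sampling with a split-half convergence diagnostic, and
    train/test prediction assessment through posterior trajectory ensembles.
    A synthetic Lotka-Volterra generator supplies reproducible test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
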