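Package: vdprhythm
Title: Dynamic van der Pol Modelling of Circadian Rhythms in Telemetry
    Temperature Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits a dynamic van der Pol oscillator model to circadian
    rhythms in telemetry temperature time series, such as tail skin
    temperature recorded in the ovariectomized rat model of menopausal
    thermoregulatory dysfunction.  The circadian component is represented
    by the second-order perturbation solution of the van der Pol equation,
    whose closed-form amplitude function interpolates from a start
    amplitude towards a limit-cycle amplitude.  Estimation is by
    pseudo-maximum likelihood with a fixed 24-hour period, a linear
    baseline trend fitted in advance, and three time-of-day noise variances
    profiled from residuals.  Group-level treatment effects on limit-cycle
    amplitudes are assessed by percentile bootstrap confidence intervals
    for mean pairwise differences and a one-sided bootstrap
    non-inferiority test on amplitude-reconstruction ratios.  A synthetic
    telemetry simulator and a Runge-Kutta integrator of the exact van der
    Pol equation are included for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
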