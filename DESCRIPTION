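Package: thermoallo
Title: Allometric and Thermal Scaling of Exploratory Movement Speed
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the allometric and thermal scaling of
    exploratory movement speed in walking ectotherms (ground beetles). Converts
    raw x-y-t tracking trajectories into one exploratory-speed value per
    individual using hysteresis speed-threshold filtering, fits and compares
    five thermal performance curve (TPC) models by multistart bounded nonlinear
    least squares with AIC selection, fits a combined body-mass power-law and
    modified Sharpe-Schoolfield model of speed as a function of mass and
    temperature, produces prediction surfaces, and tests model residuals for
    species- and habitat-group effects. Includes a synthetic-data generator
    (aggregated speed tables and two-state correlated-random-walk arena
    trajectories) emulating the study design so the full pipeline is testable
    without the original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
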