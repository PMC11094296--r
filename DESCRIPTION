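Package: mirpls
Title: Nonlinear Partial Least Squares with a Monotone Cubic Spline Inner Relation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Latent-variable regression for small, multicollinear calibration
    problems (dose-effect experiments, near-infrared spectra) in which the
    inner relation between input and output scores is nonlinear but monotone.
    Each component's inner model is a monotone piecewise-cubic regression
    spline fitted by inequality-constrained least squares; because the inner
    model is invertible, input weights are refined by regressing the score
    discrepancy on the predictors with a nested two-component linear PLS.
    Includes standard NIPALS linear PLS, calibration metrics (RMSE, MAPE,
    R-squared), leave-one-out and k-fold cross-validated grid search over
    components and knots, exact Wilcoxon signed-rank model comparison, a
    synthetic-data generator for collinear monotone-nonlinear responses, CSV
    and JSON model input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr
Config/testthat/edition: 3
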