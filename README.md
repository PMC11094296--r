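# mirpls — nonlinear PLS with a monotone cubic spline inner relation

`mirpls` is an R package for calibrating regression models on small,
strongly collinear datasets whose input-output relation is nonlinear but
monotone — the situation typical of multi-component dose-effect experiments
(a dozen samples, eight blood-concentration predictors, one pharmacological
endpoint) and of near-infrared spectroscopy (hundreds of smooth, highly
correlated wavelength channels).

## The model

Standard PLS decomposes autoscaled `X` (N x M) and `y` into bilinear
score/loading products,

    X = sum_h t_h p_h' + E,    y = sum_h u_h q_h + f,

with a linear *inner model* `u = b t` per latent component. `mirpls`
replaces that line with a **monotone C² piecewise-cubic regression spline**
`u = phi(t)` (interior knots at empirical quantiles, derivative >= 0 after
orienting the axis), fitted by inequality-constrained least squares.
Monotonicity both regularizes the inner relation and makes it invertible,
which powers the weight update: the target scores `t_hat = phi^{-1}(y q)`
define a discrepancy `e = t_hat - t = X dw`, and `dw` is estimated by a
nested two-component linear PLS of `e` on `X` (robust under collinearity
where multiple linear regression is not). The refinement loop runs at most
30 passes per component and stops when the relative score change drops
below 1e-6. Hyperparameters — the number of latent variables `A` in 1..15
and interior knots `J` in 0..5 — are chosen by cross-validated grid search
(leave-one-out for N <= 20, seeded 5-fold otherwise) minimizing RMSECV,
with ties broken toward parsimony.

The evaluation toolkit implements RMSE, MAPE, an unclamped R², the percent
RMSE improvement `k = (1 - RMSE_a / RMSE_b) * 100`, and an exact Wilcoxon
signed-rank comparison of paired absolute prediction errors.

## Worked example

```r
library(mirpls)

# synthetic world: rank-3 collinear X (N = 120, M = 8), response a tanh of a
# latent score plus noise (sd 0.1)
d <- generate_synthetic(synthetic_spec(N = 120, M = 8, latent_rank = 3,
                                       inner_function = "tanh",
                                       noise_sd_x = 0.05, noise_sd_y = 0.1,
                                       seed = 42))
train <- 1:90; test <- 91:120

m <- fit_mirpls(d$X[train, ], d$y[train], ncomp = 1, n_knots = 2)
print(m)
#> MIR-PLS model: 1 component(s), 2 interior knot(s), 8 predictors
#> Inner iterations per component: 30 (converged: FALSE)

compute_metrics(d$y[test], predict(m, d$X[test, ]))
#> n = 30  RMSE = 0.159476  MAPE = 104.315%  R2 = 0.966555

p <- fit_pls(d$X[train, ], d$y[train], ncomp = 1)
compute_metrics(d$y[test], drop(predict(p, d$X[test, ])))
#> n = 30  RMSE = 0.404879  MAPE = 117.442%  R2 = 0.78443
```

Reading the output: the monotone-inner-relation model's held-out RMSE
(0.159) approaches the simulation's noise floor (0.1) and explains 97% of
the test variance, while linear PLS with the same single component leaves
the tanh saturation unmodeled (RMSE 0.405, R² 0.784) — an RMSE improvement
of `k_improvement(0.159, 0.405)` ≈ 61%. (MAPE is large for both because
this response crosses zero; the metric is reported with that caveat
flagged.) The non-converged flag is informative, not an error: the
reference algorithm caps weight refinement at 30 passes and keeps the last
iterate.

Hyperparameter search and model persistence:

```r
cv <- cross_validate(d$X[train, ], d$y[train], lv_grid = 1:15, knot_grid = 0:5)
save_model(fit_mirpls(d$X[train, ], d$y[train], cv$best_ncomp, cv$best_knots),
           "model.json")
```

A command-line surface wraps the same operations:

```sh
Rscript -e 'mirpls::mirpls_main()' fit --x X.csv --y y.csv --lv 2 --knots 1 --out model.json
Rscript -e 'mirpls::mirpls_main()' predict --model model.json --x Xnew.csv --out yhat.csv
Rscript -e 'mirpls::mirpls_main()' cv --x X.csv --y y.csv --lv-grid 1:15 --knot-grid 0:5 --report cv.json
```

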