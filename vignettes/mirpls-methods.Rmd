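---
title: "Monotone inner-relation PLS: model, algorithm, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monotone inner-relation PLS: model, algorithm, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpls)
```

## The problem

Dose-effect experiments with multi-component preparations, and near-infrared
calibration more generally, produce data in which (i) the number of samples is
close to — or smaller than — the number of predictors, (ii) the predictors are
strongly collinear because they share a small number of underlying sources,
and (iii) the relation between exposure and response is nonlinear but, on
pharmacological grounds, monotone. Ordinary least squares fails on (i) and
(ii); linear partial least squares (PLS) handles them but misses (iii);
unconstrained nonlinear inner models (neural networks, free polynomials)
handle (iii) at the price of overfitting exactly the small-sample regime the
method is needed for.

## The model

PLS decomposes autoscaled $X \in \mathbb{R}^{N\times M}$ and
$y \in \mathbb{R}^{N}$ into bilinear score/loading products,
$X = \sum_h t_h p_h^\top + E$, $y = \sum_h u_h q_h + f$, with one *inner
model* per component linking the input scores $t_h$ to the output scores
$u_h$. In linear PLS the inner model is $u = b\,t$. Here it is a **monotone
C² piecewise-cubic regression spline** $u = \varphi(t)$: flexible enough for
saturation- and threshold-shaped dose-effect curves, but constrained enough
($\mathrm{d}u/\mathrm{d}t \ge 0$ after orienting the axis) to resist
overfitting.

Monotonicity buys a second, structural property: $\varphi$ is invertible.
That makes the *weight-updating strategy* direct. After the output loading
refresh ($q \propto \hat u^\top y$, normalized; $u = y\,q$), the target input
scores are $\hat t = \varphi^{-1}(u)$, and the discrepancy
$e = \hat t - t = X\,\Delta w$ is regressed on the current predictor residual
to obtain a weight correction. Because $X$ is collinear, that regression is
itself a **nested two-component linear PLS** rather than multiple linear
regression; $w \leftarrow (w + \Delta w)/\lVert w + \Delta w\rVert$. The
refinement loop runs at most 30 passes and stops when the relative score
change falls below $10^{-6}$; non-converged components keep their last
iterate, mirroring the reference procedure, and are flagged in the fit trace.
Response deflation subtracts the *modeled* nonlinearity
$\varphi(t)\,q$, so later components see only what the spline could not
explain.

## Fitting the monotone spline

Interior knots are placed at empirical quantiles $i/(J+1)$ of the scores
(linear-interpolation convention), so the $J+1$ polynomial pieces hold equal
sample counts (±1). $J = 0$ gives a single global cubic. The direction of
monotonicity is the sign of the sample correlation of $(t, u)$ (ties resolve
to increasing); internally a non-decreasing spline is fitted against the
oriented abscissa, and the outer weights absorb the sign.

The fit minimizes $\sum_i (u_i - \varphi(t_i))^2$ over the **full** C² cubic
spline space on those knots subject to $\varphi' \ge 0$. We deliberately do
*not* use the popular I-spline-with-nonnegative-coefficients
parameterization: nonnegative I-spline coefficients are sufficient but not
necessary for monotonicity, and on curved data the cone they span can give a
substantially larger residual than the true monotone least-squares optimum
(we measured up to 2x on tanh-shaped instances). Instead the derivative
constraint is imposed on a grid and sharpened by cutting planes at the exact
interior minima of the (piecewise-quadratic) derivative; a final "lift" —
adding the residual dip depth times the identity line, a direction that
cannot increase the objective to first order at the optimum — makes the
derivative minimum exactly nonnegative, so the returned spline is monotone
*everywhere*. The quadratic program
is solved by an in-package Lawson-Hanson route (nonnegative least squares →
least-distance programming → inequality-constrained least squares); the test
suite checks the optimum against an independent generic solver
(`mgcv::pcls`) to $10^{-5}$ relative on random instances.

Outside the fitted score range the spline extrapolates **linearly** with the
boundary derivative. Cubic extrapolation can turn around and destroy
invertibility; linear extrapolation preserves both monotonicity and the
inverse. Inversion is vectorized bracketed bisection on the non-decreasing
evaluator; on flat stretches (derivative at or below the configurable
`derivative_floor`, default 0) the preimage is an interval and its midpoint
is returned; a completely flat spline maps every query to the domain
midpoint. Queries beyond the attained range invert the linear extrapolation;
when the boundary slope is negligible relative to the spline's mean slope (a
saturated fit), inverting through it would catapult the recovered scores, so
such queries resolve to the boundary abscissa instead — this keeps the
weight-update loop bounded when a component saturates.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `ncomp` (A) | tuned in 1..15 | latent variables; bounded by `min(N-1, M)` |
| `n_knots` (J) | tuned in 0..5 | interior spline knots; 0 = one cubic piece |
| `tol` | `1e-6` | relative score-change stopping threshold |
| `max_iter` | 30 | inner refinement passes per component |
| `derivative_floor` | 0 | slope below which a stretch counts as flat for inversion |

Autoscaling uses the sample standard deviation (divisor $N-1$, the
chemometrics convention; the reference procedure says only "one-variance").
Constant predictor columns are centered, given divisor 1, and flagged — they
carry no information but must not crash an 8-predictor, 12-sample fit.

Hyperparameters are chosen by cross-validated grid search minimizing RMSECV:
leave-one-out for $N \le 20$ (the designed-experiment regime), seeded 5-fold
otherwise, with scalers and splines refitted inside every training fold (no
leakage) and out-of-fold residuals pooled before scoring. Ties are broken
toward fewer components, then fewer knots. Because components are extracted
greedily, the default search fits one model at the largest feasible `A` per
(fold, knots) and truncates — algebraically identical to refitting at every
`A`, about 8x faster.

## Evaluation toolkit

`compute_metrics()` reports RMSE, MAPE (×100%, undefined and flagged when an
observation is zero), and $R^2 = 1 - SS_{res}/SS_{tot}$ — never clamped, so a
model worse than the mean predictor shows a negative value.
`k_improvement(a, b)` is $(1 - a/b)\times 100$, the percent RMSE reduction of
model *a* over model *b*. `wilcoxon_signed_rank()` compares two models'
absolute prediction errors pairwise: zero differences are dropped (classical
Wilcoxon), ties get midranks, the null distribution is exact (convolution
over sign assignments, equivalent to full enumeration) up to 25 informative
pairs, and a tie-corrected normal approximation with continuity correction
beyond. Whether the reference analyses used signed or absolute residuals is
not stated; absolute residuals on the reported evaluation split is our
assumption, flagged here.

## What the synthetic generator does and does not emulate

`generate_synthetic()` builds $X = LV^\top + \sigma_x E$ from a rank-$r$
latent structure, so collinearity is present by construction (the condition
number diverges as $\sigma_x \to 0$); the response is a known monotone
function of a known latent score plus noise. `fixture_cm_like()` reproduces
the designed-experiment shapes (12-13 samples, 8 predictors, 1-3 endpoints
with distinct monotone links); `fixture_nir_like()` builds smooth
Gaussian-bump factor spectra (80×576 or 415×100) whose adjacent channels
correlate above 0.9. A single seed expands into separate sub-streams for
structure, X-noise, and y-noise, so changing a noise level never reshuffles
the structure.

These generators emulate *shape*, not physics: no instrument drift, no
multiplicative scatter, no heteroscedastic assay noise, no correlated
replicate structure. A green test therefore establishes that the estimator
recovers known monotone latent structure under collinearity at realistic
sizes — not that it reproduces any published benchmark number. The published
dose-effect data are withheld by their authors and the spectroscopy
benchmarks require downloads, so the package's acceptance checks are
property-based, plus one worked arithmetic check on a published RMSEP pair.

## Numerical choices and degenerate inputs

- Weight and loading normalizations are exact (`q` is ±1 for a single
  response, its sign from $\hat u^\top y$).
- A zero score discrepancy short-circuits the nested PLS: $\Delta w$ is
  exactly zero and the loop exits, making "already linear" data a true fixed
  point.
- Rank collapse (score norm below $10^{-12}$ of the residual Frobenius norm)
  truncates the model with a note rather than failing.
- Too few distinct score values for the requested knots: knots are reduced
  automatically and the reduction is recorded; fewer than four distinct
  values falls back to a monotone straight-line fit in the spline basis.
- A constant response is rejected up front.
- Everything is deterministic given its inputs; the only randomness in the
  package (fold assignment, synthetic draws) is governed by explicit seeds
  and leaves the caller's RNG state untouched.

## Known limitations

- Multi-response fitting is per-column (independent models, no shared
  deflation); joint multi-response deflation is out of scope.
- No prediction intervals or variable-importance measures.
- Single cross-validation is used for tuning; nested (double) CV, which
  would de-bias the reported RMSECV of the selected point, is future work.
- The prediction rule for new samples (sequential test-side deflation
  mirroring training) follows standard PLS practice; the reference procedure
  never specifies one.
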