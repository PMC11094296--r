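test_that("metrics match the hand-computed definitions", {
  m <- compute_metrics(c(1, 2, 3), c(1, 2, 5))
  expect_equal(m$rmse, sqrt(4 / 3))
  expect_equal(m$mape, (2 / 3) / 3 * 100)
  expect_equal(m$r2, -1)

  perfect <- compute_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mape, 0)
  expect_equal(perfect$r2, 1)

  y <- c(2, 4, 9, 1)
  expect_identical(compute_metrics(y, rep(mean(y), 4))$r2, 0)

  withzero <- compute_metrics(c(0, 1, 2), c(0.1, 1, 2))
  expect_false(withzero$mape_defined)
  expect_true(is.na(withzero$mape))

  const <- compute_metrics(c(3, 3, 3), c(1, 2, 3))
  expect_false(const$r2_defined)

  # permutation invariance
  set.seed(41)
  yy <- rnorm(12); hh <- rnorm(12)
  perm <- sample(12)
  expect_equal(compute_metrics(yy, hh)[c("rmse", "mape", "r2")],
               compute_metrics(yy[perm], hh[perm])[c("rmse", "mape", "r2")])
})

test_that("k improvement follows the (1 - a/b) * 100 convention", {
  expect_equal(round(k_improvement(0.556, 0.629), 2), 11.61)
  expect_equal(k_improvement(0.4, 0.4), 0)
  expect_equal(k_improvement(1.0, 0.5), -100)
  expect_error(k_improvement(1, 0), class = "mirpls_domain_error")
})

test_that("LOO cross-validation of a mean predictor matches the closed form", {
  set.seed(42)
  n <- 12
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rnorm(n)
  mean_fit <- function(X, y, ncomp, n_knots) structure(list(m = mean(y)), class = "meanp")
  mean_pred <- function(model, X) rep(model$m, nrow(X))
  cv <- cross_validate(X, y, lv_grid = 1, knot_grid = 0, scheme = "loo",
                       fit_fun = mean_fit, predict_fun = mean_pred)
  expect_equal(length(unique(cv$folds)), n)
  # LOO residual of the mean predictor: (n/(n-1)) (y_i - ybar)
  r <- (n / (n - 1)) * (y - mean(y))
  expect_equal(cv$best_rmsecv, sqrt(mean(r^2)))
})

test_that("k-fold assignment is seeded and deterministic", {
  set.seed(43)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- drop(X %*% c(1, -1, 2)) + rnorm(40, sd = 0.2)
  plsfit <- function(X, y, ncomp, n_knots) fit_pls(X, y, ncomp)
  plspred <- function(m, X) drop(predict(m, X))
  cv1 <- cross_validate(X, y, lv_grid = 1:3, knot_grid = 0, scheme = "kfold",
                        k = 5, seed = 9, fit_fun = plsfit, predict_fun = plspred)
  cv2 <- cross_validate(X, y, lv_grid = 1:3, knot_grid = 0, scheme = "kfold",
                        k = 5, seed = 9, fit_fun = plsfit, predict_fun = plspred)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$grid, cv2$grid)
  # and does not disturb the caller's RNG stream
  set.seed(1); a <- rnorm(1)
  set.seed(1)
  invisible(cross_validate(X, y, lv_grid = 1, knot_grid = 0, scheme = "kfold",
                           k = 4, seed = 2, fit_fun = plsfit, predict_fun = plspred))
  expect_identical(rnorm(1), a)
})

test_that("grid search selects the RMSECV minimum with parsimony tie-breaks", {
  set.seed(44)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- rnorm(30)
  # constant predictor: every grid point ties, so the first (smallest A then
  # J) must be selected
  cfit <- function(X, y, ncomp, n_knots) structure(list(m = mean(y)), class = "meanp")
  cpred <- function(model, X) rep(model$m, nrow(X))
  cv <- cross_validate(X, y, lv_grid = c(3, 1, 2), knot_grid = c(2, 0),
                       scheme = "kfold", k = 5, seed = 1,
                       fit_fun = cfit, predict_fun = cpred)
  expect_equal(cv$best_ncomp, 1)
  expect_equal(cv$best_knots, 0)
  feas <- cv$grid[cv$grid$feasible, ]
  expect_lte(cv$best_rmsecv, min(feas$rmsecv))
})

test_that("infeasible component counts are skipped and explicit folds honored", {
  set.seed(45)
  X <- matrix(rnorm(12 * 8), 12, 8)
  y <- rnorm(12)
  plsfit <- function(X, y, ncomp, n_knots) fit_pls(X, y, ncomp)
  plspred <- function(m, X) drop(predict(m, X))
  cv <- cross_validate(X, y, lv_grid = c(2, 11), knot_grid = 0, scheme = "loo",
                       fit_fun = plsfit, predict_fun = plspred)
  expect_false(cv$grid$feasible[cv$grid$ncomp == 11])
  expect_equal(cv$best_ncomp, 2)

  folds <- rep(1:3, length.out = 12)  # every-third-sample style split
  cv2 <- cross_validate(X, y, lv_grid = 2, knot_grid = 0, folds = folds,
                        fit_fun = plsfit, predict_fun = plspred)
  expect_equal(sort(unique(cv2$folds)), 1:3)
})

test_that("wilcoxon signed rank is exact for small n and handles degeneracy", {
  e <- c(0.5, 1.2, 0.3, 2.0, 0.9)
  res_same <- wilcoxon_signed_rank(e, e)
  expect_true(res_same$degenerate)
  expect_equal(res_same$p_value, 1)

  # six uniformly larger errors in model a -> two-sided exact p = 2 / 2^6
  res6 <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6), c(2, 3, 4, 5, 6, 7))
  expect_equal(res6$p_value, 2 / 64)
  expect_equal(res6$method, "exact")

  set.seed(46)
  for (i in 1:12) {
    n <- sample(5:10, 1)
    a <- rnorm(n); b <- rnorm(n)
    if (i %% 3 == 0) b[1:2] <- a[1:2]            # force zero differences
    if (i %% 4 == 0) b[3] <- -(abs(a[3]) + abs(a[1]) - abs(b[1]))  # force rank ties sometimes
    got <- wilcoxon_signed_rank(a, b)
    expect_equal(got$p_value, oracle_wilcoxon_p(a, b), tolerance = 1e-12)
    swapped <- wilcoxon_signed_rank(b, a)
    expect_equal(got$p_value, swapped$p_value, tolerance = 1e-12)
  }

  small <- wilcoxon_signed_rank(c(1, 2, 3), c(2, 3, 4))
  expect_true(small$insufficient_pairs)
  expect_true(small$p_value >= 0 && small$p_value <= 1)
})

test_that("the large-sample branch approximates the exact tail", {
  set.seed(47)
  a <- rnorm(40); b <- rnorm(40, mean = 0.8)
  res <- wilcoxon_signed_rank(a, b)
  expect_equal(res$method, "normal")
  ref <- stats::wilcox.test(abs(a), abs(b), paired = TRUE, exact = FALSE)$p.value
  expect_equal(res$p_value, ref, tolerance = 0.05)
})
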