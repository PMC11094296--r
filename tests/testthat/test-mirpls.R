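test_that("update_weights has an exact fixed point at zero discrepancy", {
  set.seed(31)
  X <- matrix(rnorm(60), 12, 5)
  w <- mirpls:::normalize(rnorm(5))
  t <- drop(X %*% w)
  upd <- update_weights(X, w, t, t)
  expect_identical(upd$delta_w, numeric(5))
  expect_identical(upd$w_new, w)
})

test_that("the weight correction equals the nested 2-LV PLS oracle", {
  set.seed(32)
  for (i in 1:5) {
    X <- matrix(rnorm(20 * 6), 20, 6)
    w <- mirpls:::normalize(rnorm(6))
    t <- drop(X %*% w)
    d <- rnorm(6, sd = 0.3)
    e <- drop(X %*% d)
    upd <- update_weights(X, w, t, t + e)
    expect_lt(max(abs(upd$delta_w - oracle_pls1_coef(X, e, 2))), 1e-10)
    expect_equal(sqrt(sum(upd$w_new^2)), 1, tolerance = 1e-12)
  }
})

test_that("fit_mirpls recovers a noiseless single-latent monotone relation", {
  d <- generate_synthetic(synthetic_spec(
    N = 100, M = 8, latent_rank = 3, inner_function = "tanh",
    noise_sd_x = 0, noise_sd_y = 0, seed = 11))
  m <- fit_mirpls(d$X, d$y, ncomp = 1, n_knots = 2)
  expect_gte(compute_metrics(d$y, fitted(m))$r2, 0.99)
})

test_that("components obey the loop contracts, orthogonality, and deflation algebra", {
  set.seed(33)
  X <- matrix(rnorm(30 * 6), 30, 6)
  y <- tanh(X[, 1] + X[, 2]) + 0.3 * X[, 3] + rnorm(30, sd = 0.1)
  m <- fit_mirpls(X, y, ncomp = 3, n_knots = 1)

  its <- vapply(m$components, `[[`, integer(1), "iterations")
  expect_true(all(its <= 30))
  for (h in seq_along(m$components)) {
    if (m$components[[h]]$converged) {
      tr <- m$trace[m$trace$component == h, ]
      expect_lt(tr$score_change[nrow(tr)], 1e-6)
    }
  }

  Tm <- vapply(m$components, `[[`, numeric(30), "t_train")
  G <- crossprod(Tm)
  norms <- sqrt(diag(G))
  off <- abs(G[upper.tri(G)])
  expect_true(all(off <= 1e-6 * outer(norms, norms)[upper.tri(G)]))

  Xs <- autoscale(X)$scaled
  recon <- Reduce(`+`, lapply(m$components, function(c) tcrossprod(c$t_train, c$p)))
  expect_lt(max(abs(Xs - (recon + m$x_residual))), 1e-10)
})

test_that("prediction mirrors training and is invariant to affine predictor rescaling", {
  set.seed(34)
  X <- matrix(rnorm(25 * 5), 25, 5)
  y <- exp(0.5 * (X[, 1] - X[, 4])) + rnorm(25, sd = 0.1)
  m <- fit_mirpls(X, y, ncomp = 2, n_knots = 1)
  expect_lt(max(abs(predict(m, X) - fitted(m))), 1e-10)
  expect_lt(abs(predict(m, X[7, , drop = FALSE]) - fitted(m)[7]), 1e-10)

  scale_f <- c(3, 0.2, 1, 5, 10); shift <- rnorm(5)
  Xa <- sweep(sweep(X, 2, scale_f, "*"), 2, shift, "+")
  ma <- fit_mirpls(Xa, y, ncomp = 2, n_knots = 1)
  expect_lt(max(abs(predict(ma, Xa) - predict(m, X))), 1e-8)

  expect_error(predict(m, X[, 1:4]), class = "mirpls_shape_error")
})

test_that("the fit is deterministic: identical reruns are bit-identical", {
  set.seed(35)
  X <- matrix(rnorm(20 * 6), 20, 6)
  y <- tanh(X[, 2]) + rnorm(20, sd = 0.1)
  m1 <- fit_mirpls(X, y, ncomp = 2, n_knots = 1)
  m2 <- fit_mirpls(X, y, ncomp = 2, n_knots = 1)
  expect_identical(m1$components[[1]]$w, m2$components[[1]]$w)
  expect_identical(fitted(m1), fitted(m2))
})

test_that("multiresponse fitting is per-column and order-preserving", {
  set.seed(36)
  X <- matrix(rnorm(15 * 6), 15, 6)
  y1 <- tanh(X[, 1]) + rnorm(15, sd = 0.1)
  Ydup <- cbind(a = y1, b = y1)
  models <- fit_mirpls_multiresponse(X, Ydup, ncomp = 1, n_knots = 1)
  expect_named(models, c("a", "b"))
  expect_lt(max(abs(predict(models$a, X) - predict(models$b, X))), 1e-10)

  Y3 <- cbind(y1, X[, 2] + rnorm(15, sd = 0.1), exp(X[, 3] / 2) + rnorm(15, sd = 0.1))
  models3 <- fit_mirpls_multiresponse(X, Y3, ncomp = c(1, 1, 2), n_knots = c(1, 0, 2))
  expect_length(models3, 3)
  expect_equal(models3[[3]]$n_knots, 2)
})

test_that("degenerate inputs are rejected", {
  set.seed(37)
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_mirpls(X, rep(1, 10), 1, 0), class = "mirpls_validation_error")
  expect_error(fit_mirpls(X, rnorm(10), 3, 0), class = "mirpls_parameter_error")
})

test_that("an exactly linear inner relation exits the refinement loop immediately", {
  # y proportional to a left singular vector of scaled X: the first scores t
  # are then exactly proportional to u, the J = 0 spline fit is that line,
  # t_hat = t up to root-finder precision, delta_w = 0, and the loop exits
  # after a single pass with w unchanged
  set.seed(38)
  X <- matrix(rnorm(40 * 4), 40, 4)
  y <- svd(scale(X))$u[, 1]
  m <- fit_mirpls(X, y, ncomp = 1, n_knots = 0)
  expect_true(m$components[[1]]$converged)
  expect_equal(m$components[[1]]$iterations, 1L)
  expect_equal(m$trace$weight_correction_norm[1], 0)
})
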