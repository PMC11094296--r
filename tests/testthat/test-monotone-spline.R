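test_that("place_knots follows the equal-count quantile rule", {
  kv <- place_knots(1:10, 1)
  expect_equal(kv$interior, 5.5)
  expect_equal(kv$boundary, c(1, 10))

  expect_length(place_knots(rnorm(20), 0)$interior, 0)

  # 100 points, 3 knots -> four segments of 25 points each
  set.seed(21)
  t <- sort(rnorm(100))
  kv3 <- place_knots(t, 3)
  breaks <- c(-Inf, kv3$interior, Inf)
  counts <- table(cut(t, breaks))
  expect_true(max(counts) - min(counts) <= 1)
  expect_equal(sum(counts), 100)

  expect_error(place_knots(c(1, 1, 1, 2), 3), class = "mirpls_knot_error")
})

test_that("data already in the monotone family are reproduced exactly", {
  t <- seq(-2, 2, length.out = 30)
  up <- fit_monotone_spline(t, t, J = 1)
  expect_equal(up$direction, 1)
  expect_lt(max(abs(up$fitted - t)), 1e-8)
  grid <- seq(-2, 2, length.out = 512)
  expect_true(all(up$direction * eval_spline_deriv(up, grid) >= -1e-9))

  dn <- fit_monotone_spline(t, -t, J = 1)
  expect_equal(dn$direction, -1)
  expect_lt(max(abs(dn$fitted - (-t))), 1e-8)
})

test_that("fitted SSE matches the constrained least-squares oracle", {
  set.seed(22)
  shapes <- list(function(z) tanh(1.5 * z),
                 function(z) -tanh(2 * z),
                 function(z) z + 0.3 * sin(3 * z),
                 function(z) exp(z / 2))
  for (i in 1:20) {
    n <- sample(15:60, 1)
    J <- sample(0:3, 1)
    t <- sort(rnorm(n))
    g <- shapes[[sample(length(shapes), 1)]]
    u <- g(t) + rnorm(n, sd = 0.05)
    fit <- fit_monotone_spline(t, u, J)
    sse_oracle <- oracle_monotone_sse(t, u, J)
    expect_lt(abs(fit$sse - sse_oracle) / max(sse_oracle, 1e-12), 1e-5)
    # monotonicity certificate on a 512-point grid
    grid <- seq(fit$fitted_domain[1], fit$fitted_domain[2], length.out = 512)
    expect_gte(min(fit$direction * eval_spline_deriv(fit, grid)), -1e-9)
    # never worse than the best monotone straight line
    sl <- cov(t, u) / var(t)
    if (sign(sl) != fit$direction) sl <- 0
    sse_line <- sum((u - (mean(u) + sl * (t - mean(t))))^2)
    expect_lte(fit$sse, sse_line + 1e-9)
  }
})

test_that("splines are C2 at interior knots (finite differences)", {
  set.seed(23)
  t <- sort(runif(60, -3, 3))
  u <- tanh(t) + rnorm(60, sd = 0.03)
  fit <- fit_monotone_spline(t, u, J = 2)
  h <- 1e-5
  for (kn in fit$knots$interior) {
    x <- fit$direction * kn
    f <- function(z) eval_spline(fit, z)
    expect_lt(abs(f(x + h) - f(x - h)) / max(abs(f(x)), 1), 1e-3)
    d_left <- (f(x) - f(x - h)) / h
    d_right <- (f(x + h) - f(x)) / h
    expect_lt(abs(d_right - d_left), 1e-3)  # first derivative continuous
    dd_left <- (f(x) - 2 * f(x - h) + f(x - 2 * h)) / h^2
    dd_right <- (f(x + 2 * h) - 2 * f(x + h) + f(x)) / h^2
    expect_lt(abs(dd_right - dd_left) / max(abs(dd_left), 1), 5e-2)
  }
})

test_that("evaluation is exact at training points and extrapolates linearly", {
  set.seed(24)
  t <- sort(rnorm(40))
  u <- exp(t / 2) + rnorm(40, sd = 0.05)
  fit <- fit_monotone_spline(t, u, J = 1)
  expect_identical(eval_spline(fit, t), fit$fitted)

  hi <- fit$fitted_domain[2]
  slope_hi <- eval_spline_deriv(fit, hi)
  for (delta in c(0.1, 0.5, 2)) {
    expect_equal(eval_spline(fit, hi + delta),
                 eval_spline(fit, hi) + slope_hi * delta, tolerance = 1e-10)
  }

  q <- sort(runif(200, fit$fitted_domain[1] - 1, fit$fitted_domain[2] + 1))
  vals <- fit$direction * eval_spline(fit, q)
  expect_true(all(diff(vals) >= -1e-9))
})

test_that("inversion round-trips, including flat and decreasing splines", {
  ident <- fit_monotone_spline(seq(-1, 1, length.out = 20),
                               seq(-1, 1, length.out = 20), J = 0)
  uq <- runif(50, -1, 1)
  expect_lt(max(abs(invert_spline(ident, uq) - uq)), 1e-10)

  set.seed(25)
  for (J in 0:2) {
    t <- sort(rnorm(50))
    u <- tanh(2 * t) * sample(c(-1, 1), 1) + rnorm(50, sd = 0.05)
    fit <- fit_monotone_spline(t, u, J)
    rng <- range(fit$boundary_values)
    uu <- runif(100, rng[1], rng[2])
    back <- eval_spline(fit, invert_spline(fit, uu))
    expect_lt(max(abs(back - uu) / (1 + abs(uu))), 1e-8)
    # beyond-range queries invert the linear extrapolation; with a flat
    # (saturated) boundary no preimage exists and the boundary is returned
    u_out <- rng[1] - 0.5 * diff(rng)
    slope_low <- fit$boundary_slopes[1]
    if (slope_low > 1e-6) {
      expect_equal(eval_spline(fit, invert_spline(fit, u_out)), u_out,
                   tolerance = 1e-8)
    } else {
      t_bnd <- fit$direction * fit$s_domain[1]
      expect_equal(invert_spline(fit, u_out), t_bnd, tolerance = 1e-10)
    }
  }

  flat <- fit_monotone_spline(1:10, rep(2, 10), J = 1)
  expect_equal(invert_spline(flat, c(-3, 2, 9)), rep(5.5, 3))
})

test_that("degenerate inputs are rejected or repaired", {
  expect_error(fit_monotone_spline(rep(1, 10), rnorm(10), 1),
               class = "mirpls_degenerate_error")
  # few distinct values: knots reduced, noted
  t <- rep(c(1, 2, 3, 4, 5), each = 4)
  fit <- fit_monotone_spline(t, t + rnorm(20, sd = 0.01), J = 4)
  expect_true(length(fit$notes) > 0)
  expect_lt(length(fit$knots$interior), 4)
})
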