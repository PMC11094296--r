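# Calibration metrics, cross-validated grid search over (components, knots),
# and exact Wilcoxon signed-rank model comparison.

#' Calibration metrics: RMSE, MAPE, R-squared
#'
#' `rmse = sqrt(sum((yhat - y)^2) / N)`; `mape = mean(|y - yhat| / |y|) * 100`
#' (undefined, and flagged, when any observation is zero);
#' `r2 = 1 - SS_res / SS_tot` with the total sum of squares about the mean of
#' `y` (undefined when `y` is constant). R-squared is deliberately not
#' clamped: values below zero indicate a model worse than the mean predictor
#' and are reported as such.
#'
#' @param y observed values.
#' @param yhat predicted values, same length.
#' @return Object of class `mirpls_metrics`: list with `rmse`, `mape`, `r2`,
#'   `n`, and logical flags `mape_defined`, `r2_defined`.
#' @examples
#' compute_metrics(c(1, 2, 3), c(1, 2, 5))
#' @export
compute_metrics <- function(y, yhat) {
  stopifnot(is.numeric(y), is.numeric(yhat), length(y) == length(yhat),
            length(y) >= 2L)
  if (any(!is.finite(y)) || any(!is.finite(yhat))) {
    mirpls_error("metrics require finite inputs", "mirpls_validation_error")
  }
  n <- length(y)
  rmse <- sqrt(sum((yhat - y)^2) / n)
  mape_defined <- all(y != 0)
  mape <- if (mape_defined) mean(abs((y - yhat) / y)) * 100 else NA_real_
  sstot <- sum((y - mean(y))^2)
  r2_defined <- sstot > 0
  r2 <- if (r2_defined) 1 - sum((y - yhat)^2) / sstot else NA_real_
  structure(list(rmse = rmse, mape = mape, r2 = r2, n = n,
                 mape_defined = mape_defined, r2_defined = r2_defined),
            class = "mirpls_metrics")
}

#' @export
print.mirpls_metrics <- function(x, ...) {
  cat(sprintf("n = %d  RMSE = %.6g  MAPE = %s  R2 = %s\n", x$n, x$rmse,
              if (x$mape_defined) sprintf("%.6g%%", x$mape) else "undefined",
              if (x$r2_defined) sprintf("%.6g", x$r2) else "undefined"))
  invisible(x)
}

#' RMSE improvement of one model over another
#'
#' `k = (1 - rmse_a / rmse_b) * 100`, in percent: positive when model `a`
#' (conventionally the monotone inner-relation model) improves on model `b`.
#'
#' @param rmse_a RMSE of the model of interest.
#' @param rmse_b RMSE of the comparator; must be positive.
#' @return Percentage improvement (negative when `a` is worse).
#' @examples
#' k_improvement(0.556, 0.629)  # 11.61
#' @export
k_improvement <- function(rmse_a, rmse_b) {
  stopifnot(is.numeric(rmse_a), is.numeric(rmse_b))
  if (any(rmse_b <= 0)) {
    mirpls_error("comparator RMSE must be positive", "mirpls_domain_error")
  }
  (1 - rmse_a / rmse_b) * 100
}

# Fold assignment: LOO gives each sample its own fold; k-fold partitions
# uniformly at random under the given seed (sizes differ by at most one).
make_folds <- function(n, scheme, k, seed) {
  if (scheme == "loo") return(seq_len(n))
  if (k > n) mirpls_error("`k` must not exceed the number of samples", "mirpls_parameter_error")
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Cross-validated grid search over components and knots
#'
#' For every `(A, J)` grid point, out-of-fold predictions are assembled over
#' all folds (scalers and everything else are refitted within each training
#' fold, so no information leaks from held-out samples), pooled, and scored
#' with [compute_metrics()]. The selected point minimizes RMSECV; ties break
#' toward smaller `A`, then smaller `J` (parsimony order). Grid points whose
#' `A` exceeds what the smallest training fold supports are marked infeasible
#' and skipped.
#'
#' The default scheme is leave-one-out for `N <= 20` samples (the designed-
#' experiment regime) and seeded 5-fold otherwise (the spectroscopy regime).
#' An explicit `folds` vector (e.g. every-third-sample splits) overrides both.
#'
#' @param X predictor matrix; `y` response vector.
#' @param y numeric response vector.
#' @param lv_grid integer vector of candidate component counts (default 1:15).
#' @param knot_grid integer vector of candidate interior knot counts
#'   (default 0:5). Ignored (fixed at 0) when `fit_fun` does not use knots.
#' @param scheme `"auto"`, `"loo"`, or `"kfold"`.
#' @param k number of folds for `"kfold"` (default 5).
#' @param seed integer seed for the fold assignment (default 1).
#' @param folds optional explicit fold-id vector of length `nrow(X)`.
#' @param fit_fun function `(X, y, ncomp, n_knots) -> model`; defaults to
#'   [fit_mirpls()]. Pass a wrapper around [fit_pls()] to tune the linear
#'   baseline on the same folds.
#' @param predict_fun function `(model, X) -> numeric`; defaults to
#'   `predict`.
#' @return Object of class `mirpls_cv`: `grid` (data frame with `ncomp`,
#'   `n_knots`, `rmsecv`, `mapecv`, `feasible`), `best_ncomp`, `best_knots`,
#'   `best_rmsecv`, `scheme`, `folds`, `seed`.
#' @export
cross_validate <- function(X, y, lv_grid = 1:15, knot_grid = 0:5,
                           scheme = c("auto", "loo", "kfold"), k = 5L,
                           seed = 1L, folds = NULL,
                           fit_fun = NULL, predict_fun = NULL) {
  X <- validate_matrix(X, "X")
  y <- drop(as_numeric_matrix(y, "y"))
  stopifnot(length(y) == nrow(X), length(lv_grid) >= 1L, length(knot_grid) >= 1L)
  scheme <- match.arg(scheme)
  n <- nrow(X)
  if (scheme == "auto") scheme <- if (n <= 20L) "loo" else "kfold"
  if (is.null(folds)) {
    folds <- make_folds(n, scheme, k, seed)
  } else {
    stopifnot(length(folds) == n)
    folds <- as.integer(factor(folds))
  }
  fold_ids <- sort(unique(folds))
  min_train <- n - max(tabulate(folds))
  # Default route: MIR-PLS components are extracted greedily, so one fit at
  # the largest feasible A per (fold, knots) contains every smaller-A model
  # exactly; out-of-fold predictions for all A come from truncation. A custom
  # fit_fun cannot be assumed nested, so it takes the general per-point loop.
  use_nested <- is.null(fit_fun) && is.null(predict_fun)
  if (is.null(fit_fun)) {
    fit_fun <- function(X, y, ncomp, n_knots) fit_mirpls(X, y, ncomp, n_knots)
  }
  if (is.null(predict_fun)) {
    predict_fun <- function(model, X) drop(stats::predict(model, X))
  }

  lv_grid <- sort(unique(as.integer(lv_grid)))
  knot_grid <- sort(unique(as.integer(knot_grid)))
  grid <- expand.grid(ncomp = lv_grid, n_knots = knot_grid)
  grid <- grid[order(grid$ncomp, grid$n_knots), , drop = FALSE]
  rownames(grid) <- NULL
  grid$rmsecv <- NA_real_
  grid$mapecv <- NA_real_
  grid$feasible <- TRUE
  A_bound <- min(min_train - 1L, ncol(X))

  if (use_nested) {
    lv_feas <- lv_grid[lv_grid <= A_bound]
    if (length(lv_feas)) {
      A_top <- max(lv_feas)
      preds <- array(NA_real_, c(n, length(lv_feas), length(knot_grid)))
      for (f in fold_ids) {
        test_idx <- which(folds == f)
        train_idx <- which(folds != f)
        for (jj in seq_along(knot_grid)) {
          m <- tryCatch(fit_mirpls(X[train_idx, , drop = FALSE], y[train_idx],
                                   ncomp = A_top, n_knots = knot_grid[jj]),
                        error = function(e) NULL)
          if (is.null(m)) next
          for (aa in seq_along(lv_feas)) {
            if (lv_feas[aa] <= m$n_components) {
              preds[test_idx, aa, jj] <-
                predict(m, X[test_idx, , drop = FALSE], ncomp = lv_feas[aa])
            }
          }
        }
      }
      for (g in seq_len(nrow(grid))) {
        aa <- match(grid$ncomp[g], lv_feas)
        jj <- match(grid$n_knots[g], knot_grid)
        if (is.na(aa)) { grid$feasible[g] <- FALSE; next }
        pred <- preds[, aa, jj]
        if (any(is.na(pred))) { grid$feasible[g] <- FALSE; next }
        met <- compute_metrics(y, pred)
        grid$rmsecv[g] <- met$rmse
        grid$mapecv[g] <- met$mape
      }
    } else {
      grid$feasible <- FALSE
    }
  } else {
    for (g in seq_len(nrow(grid))) {
      A <- grid$ncomp[g]; J <- grid$n_knots[g]
      if (A > A_bound) {
        grid$feasible[g] <- FALSE
        next
      }
      pred <- rep(NA_real_, n)
      ok <- TRUE
      for (f in fold_ids) {
        test_idx <- which(folds == f)
        train_idx <- which(folds != f)
        m <- tryCatch(fit_fun(X[train_idx, , drop = FALSE], y[train_idx], A, J),
                      error = function(e) NULL)
        if (is.null(m)) { ok <- FALSE; break }
        pred[test_idx] <- predict_fun(m, X[test_idx, , drop = FALSE])
      }
      if (!ok || any(is.na(pred))) {
        grid$feasible[g] <- FALSE
        next
      }
      met <- compute_metrics(y, pred)
      grid$rmsecv[g] <- met$rmse
      grid$mapecv[g] <- met$mape
    }
  }

  feas <- which(grid$feasible)
  if (!length(feas)) {
    mirpls_error("no feasible grid point", "mirpls_parameter_error")
  }
  # parsimony tie-break: the grid is sorted by (ncomp, n_knots), so the first
  # minimizer is the smallest-A, then smallest-J one
  best <- feas[which.min(grid$rmsecv[feas])]
  structure(list(
    grid = grid,
    best_ncomp = grid$ncomp[best],
    best_knots = grid$n_knots[best],
    best_rmsecv = grid$rmsecv[best],
    best_mapecv = grid$mapecv[best],
    scheme = scheme,
    folds = folds,
    seed = seed
  ), class = "mirpls_cv")
}

#' @export
print.mirpls_cv <- function(x, ...) {
  cat(sprintf("Cross-validation (%s, %d folds): best ncomp = %d, knots = %d, RMSECV = %.6g\n",
              x$scheme, length(unique(x$folds)), x$best_ncomp, x$best_knots, x$best_rmsecv))
  invisible(x)
}

# Null distribution of the signed-rank statistic V (sum of positive ranks)
# by dynamic programming over doubled midranks (doubling makes tied midranks
# integral). Returns the probability vector over 2V = 0..sum(2r).
signed_rank_null <- function(ranks2) {
  total <- sum(ranks2)
  probs <- numeric(total + 1L)
  probs[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), probs[seq_len(total + 1L - r)])
    probs <- (probs + shifted) / 2
  }
  probs
}

#' Wilcoxon signed-rank comparison of paired prediction errors
#'
#' Two-sided paired test on the differences of absolute prediction errors of
#' two models evaluated on the same samples. Zero differences are dropped
#' before ranking (classical Wilcoxon treatment); ties receive midranks. The
#' null distribution is exact (full enumeration via convolution over sign
#' assignments) for up to 25 retained pairs and a normal approximation with
#' tie correction and continuity correction above that. The two-sided p-value
#' is `min(1, 2 * min(P(V <= v), P(V >= v)))`.
#'
#' @param errors_a,errors_b paired prediction errors (signs are ignored:
#'   absolute values are compared).
#' @return Object of class `mirpls_comparison`: `statistic` (V, the sum of
#'   positive ranks), `p_value`, `n_pairs` (after zero removal), `method`
#'   (`"exact"` or `"normal"`), and flags `degenerate` (all differences zero)
#'   and `insufficient_pairs` (< 5 retained pairs).
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6), c(2, 3, 4, 5, 6, 7))$p_value  # 0.03125
#' @export
wilcoxon_signed_rank <- function(errors_a, errors_b) {
  stopifnot(is.numeric(errors_a), is.numeric(errors_b),
            length(errors_a) == length(errors_b))
  d <- abs(errors_a) - abs(errors_b)
  if (any(!is.finite(d))) mirpls_error("errors must be finite", "mirpls_validation_error")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(list(statistic = 0, p_value = 1, n_pairs = 0L,
                          method = "degenerate", degenerate = TRUE,
                          insufficient_pairs = TRUE),
                     class = "mirpls_comparison"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25L) {
    probs <- signed_rank_null(as.integer(round(2 * r)))
    v2 <- as.integer(round(2 * v))
    p_le <- sum(probs[seq_len(v2 + 1L)])
    p_ge <- sum(probs[(v2 + 1L):length(probs)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  structure(list(statistic = v, p_value = p, n_pairs = n, method = method,
                 degenerate = FALSE, insufficient_pairs = n < 5L),
            class = "mirpls_comparison")
}

#' @export
print.mirpls_comparison <- function(x, ...) {
  cat(sprintf("Wilcoxon signed rank (%s): V = %g, n = %d, p = %.4g\n",
              x$method, x$statistic, x$n_pairs, x$p_value))
  if (x$degenerate) cat("  (all paired differences zero)\n")
  else if (x$insufficient_pairs) cat("  (fewer than 5 informative pairs)\n")
  invisible(x)
}
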