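# Standard NIPALS linear PLS. Used three ways in this package: as the
# baseline comparator, as the nested regression inside the monotone-PLS
# weight update, and as the linear limit in equivalence tests.

# Core NIPALS on matrices that are already centered/scaled (or deliberately
# raw, for the nested weight-update regression, where the target e = X dw has
# no intercept). Extracts up to A components, truncating when the X scores
# collapse.
nipals_core <- function(X, Y, A, tol = 1e-10, max_iter = 500L) {
  N <- nrow(X); M <- ncol(X); K <- ncol(Y)
  W <- matrix(0, M, A); P <- matrix(0, M, A); Q <- matrix(0, K, A)
  b <- numeric(A)
  Tm <- matrix(0, N, A); Um <- matrix(0, N, A)
  Xh <- X; Yh <- Y
  normX <- sqrt(sum(X^2))
  notes <- character(0)
  A_eff <- 0L
  for (h in seq_len(A)) {
    u <- Yh[, which.max(apply(Yh, 2, stats::var))]
    if (sum(u^2) == 0) {
      notes <- c(notes, sprintf("component %d: response residual exhausted", h))
      break
    }
    t_old <- NULL
    for (it in seq_len(if (K == 1L) 1L else max_iter)) {
      w <- normalize(drop(crossprod(Xh, u)) / sum(u^2))
      t <- drop(Xh %*% w)
      if (sum(t^2) == 0) break
      q <- normalize(drop(crossprod(Yh, t)) / sum(t^2))
      u <- drop(Yh %*% q)
      if (!is.null(t_old) && l2norm(t - t_old) <= tol * l2norm(t)) break
      t_old <- t
    }
    if (l2norm(t) < 1e-12 * max(normX, 1)) {
      notes <- c(notes, sprintf("component %d: score norm collapsed, model truncated", h))
      break
    }
    bh <- sum(u * t) / sum(t * t)
    p <- drop(crossprod(Xh, t)) / sum(t * t)
    W[, h] <- w; P[, h] <- p; Q[, h] <- q; b[h] <- bh
    Tm[, h] <- t; Um[, h] <- u
    Xh <- Xh - tcrossprod(t, p)
    Yh <- Yh - bh * tcrossprod(t, q)
    A_eff <- h
  }
  keep <- seq_len(A_eff)
  list(W = W[, keep, drop = FALSE], P = P[, keep, drop = FALSE],
       Q = Q[, keep, drop = FALSE], b = b[keep],
       scores_x = Tm[, keep, drop = FALSE], scores_y = Um[, keep, drop = FALSE],
       n_components = A_eff, notes = notes)
}

# Regression coefficient matrix (M x K) on the preprocessed scale:
# Yhat = X W (P'W)^{-1} diag(b) Q'.
nipals_coef <- function(core) {
  if (core$n_components == 0L) {
    mirpls_error("no components extracted", "mirpls_rank_error")
  }
  R <- core$W %*% solve(crossprod(core$P, core$W))
  R %*% (core$b * t(core$Q))
}

#' Fit a linear PLS regression (NIPALS)
#'
#' Decomposes autoscaled `X` and `Y` into bilinear score/loading products with
#' a linear inner relation per component, extracting components one at a time
#' with deflation. Weight vectors have unit norm; X-score vectors are mutually
#' orthogonal.
#'
#' @param X numeric predictor matrix, N x M.
#' @param Y numeric response matrix or vector, N x K.
#' @param ncomp number of latent variables A, `1 <= A <= min(N - 1, M)`.
#' @return An object of class `pls_model` with elements `weights`,
#'   `x_loadings`, `y_loadings`, `inner_slopes`, score matrices, the fitted
#'   scalers, `fitted` values on the original response scale, and `notes`
#'   recording any truncation.
#' @seealso [predict.pls_model()], [pls_coefficient_vector()]
#' @examples
#' X <- matrix(rnorm(40), 10, 4)
#' y <- X[, 1] + rnorm(10, sd = 0.1)
#' m <- fit_pls(X, y, ncomp = 2)
#' cor(fitted(m), y)
#' @export
fit_pls <- function(X, Y, ncomp) {
  X <- validate_matrix(X, "X")
  Y <- validate_matrix(as_numeric_matrix(Y, "Y"), "Y", min_rows = 2L)
  if (nrow(X) != nrow(Y)) {
    mirpls_error("`X` and `Y` must have the same number of rows", "mirpls_shape_error")
  }
  A_max <- min(nrow(X) - 1L, ncol(X))
  if (length(ncomp) != 1L || !is.finite(ncomp) || ncomp < 1 || ncomp > A_max || ncomp != round(ncomp)) {
    mirpls_error(sprintf("`ncomp` must be an integer in [1, %d]", A_max),
                 "mirpls_parameter_error")
  }
  sx <- autoscale(X)
  sy <- autoscale(Y)
  if (any(sy$scaler$zero_variance_mask)) {
    mirpls_error("`Y` has a constant column; nothing to model", "mirpls_validation_error")
  }
  core <- nipals_core(sx$scaled, sy$scaled, as.integer(ncomp))
  if (core$n_components == 0L) {
    mirpls_error("no PLS component could be extracted (X has no variance?)",
                 "mirpls_rank_error")
  }
  coefs <- nipals_coef(core)
  fitted_scaled <- sx$scaled %*% coefs
  model <- structure(list(
    n_components = core$n_components,
    weights = core$W,
    x_loadings = core$P,
    y_loadings = core$Q,
    inner_slopes = core$b,
    scores_x = core$scores_x,
    scores_y = core$scores_y,
    coefficients = coefs,
    x_scaler = sx$scaler,
    y_scaler = sy$scaler,
    fitted = unscale(fitted_scaled, sy$scaler),
    notes = core$notes
  ), class = "pls_model")
  model
}

#' @export
fitted.pls_model <- function(object, ...) object$fitted

#' Predict from a fitted linear PLS model
#'
#' @param object a `pls_model`.
#' @param newdata matrix with the same number of columns as the training data.
#' @param ... unused.
#' @return Matrix of predictions (N_new x K) on the original response scale.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as_numeric_matrix(newdata, "newdata")
  if (ncol(newdata) != length(object$x_scaler$means)) {
    mirpls_error(sprintf("`newdata` has %d columns, model expects %d",
                         ncol(newdata), length(object$x_scaler$means)),
                 "mirpls_shape_error")
  }
  Xs <- autoscale(newdata, scaler = object$x_scaler)$scaled
  unscale(Xs %*% object$coefficients, object$y_scaler)
}

#' Regression coefficient vector of a single-response PLS model
#'
#' Returns the length-M vector `beta` such that predictions equal
#' `scale(Xnew) %*% beta`, back-transformed with the response scaler.
#'
#' @param model a fitted `pls_model` with one response column.
#' @return Numeric vector of length M (on the autoscaled X/y scale).
#' @export
pls_coefficient_vector <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  if (ncol(model$coefficients) != 1L) {
    mirpls_error("coefficient vector is defined for single-response models only",
                 "mirpls_shape_error")
  }
  drop(model$coefficients)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("Linear PLS model: %d component(s), %d predictors, %d response(s)\n",
              x$n_components, nrow(x$weights), nrow(x$y_loadings)))
  if (length(x$notes)) cat("Notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
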