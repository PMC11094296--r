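# The monotone inner-relation PLS estimator.
#
# Outer loop: extract latent components one at a time with deflation, exactly
# as in linear NIPALS. Inner loop, per component: fit a monotone cubic spline
# u = phi(t); compute the output loading q from the spline predictions;
# refresh the output scores u = y q; exploit invertibility to get the target
# input scores t_hat = phi^{-1}(u); and correct the input weights by the
# coefficient vector of a nested two-component linear PLS of the score
# discrepancy e = t_hat - t on the current predictor residual. The nested PLS
# (rather than multiple linear regression) is what keeps the weight update
# stable on multicollinear data.

#' Weight correction via nested linear PLS
#'
#' Computes the discrepancy `e = t_hat - t` between the inverse-spline target
#' scores and the current scores, regresses it on the predictor residual with
#' a nested linear PLS of `min(2, achievable)` components, and adds the
#' resulting coefficient vector to the weights. The nested regression runs on
#' the matrices as given (no re-centering): `e = X dw` has no intercept.
#'
#' @param X predictor residual matrix for the current component (N x M).
#' @param w current unit weight vector.
#' @param t current input scores, `t = X %*% w`.
#' @param t_hat target input scores from the inverted inner model.
#' @return List with `w_new` (unit norm) and `delta_w`; when the discrepancy
#'   is numerically zero the correction is exactly zero and `w` is returned
#'   unchanged.
#' @export
update_weights <- function(X, w, t, t_hat) {
  X <- as_numeric_matrix(X, "X")
  update_weights_core(X, w, t, t_hat)
}

update_weights_core <- function(X, w, t, t_hat) {
  e <- t_hat - t
  scale_e <- l2norm(e)
  if (!is.finite(scale_e) || scale_e <= 1e-12 * max(l2norm(t), 1)) {
    return(list(w_new = w, delta_w = numeric(length(w)), degenerate = TRUE))
  }
  core <- nipals_core(X, matrix(e, ncol = 1), A = min(2L, ncol(X), nrow(X) - 1L))
  if (core$n_components == 0L) {
    return(list(w_new = w, delta_w = numeric(length(w)), degenerate = TRUE))
  }
  delta_w <- drop(nipals_coef(core))
  list(w_new = normalize(w + delta_w), delta_w = delta_w, degenerate = FALSE)
}

#' Fit a monotone inner-relation PLS (MIR-PLS) model
#'
#' Single-response nonlinear PLS in which each component's inner relation is
#' a monotone cubic regression spline with `n_knots` quantile-placed interior
#' knots. Inputs are autoscaled; components are extracted with NIPALS-style
#' deflation; within each component the weights are refined iteratively (at
#' most `max_iter` passes, stopping when the relative score change drops
#' below `tol`) using the invertibility of the monotone inner model. Response
#' deflation subtracts the modeled nonlinearity `phi(t)` (not the raw output
#' scores).
#'
#' @param X numeric predictor matrix, N x M.
#' @param y numeric response vector (single response).
#' @param ncomp number of latent variables A, `1 <= A <= min(N - 1, M)`.
#' @param n_knots number of interior spline knots J (`0` = one cubic piece).
#' @param tol relative score-change convergence threshold (default `1e-6`).
#' @param max_iter maximum inner-loop iterations per component (default 30).
#'   Non-converged components keep their last iterate; the `trace` records
#'   `converged = FALSE`.
#' @return An object of class `mirpls_model`: per-component weights `w`,
#'   loadings `p`, output loading sign `q`, fitted `monotone_spline` inner
#'   models, training scores, scalers, fitted values, and an iteration
#'   `trace` data frame.
#' @seealso [predict.mirpls_model()], [cross_validate()]
#' @examples
#' d <- generate_synthetic(synthetic_spec(N = 60, M = 8, latent_rank = 3,
#'                                        inner_function = "tanh", seed = 1))
#' m <- fit_mirpls(d$X, d$y, ncomp = 1, n_knots = 2)
#' compute_metrics(d$y, fitted(m))$r2
#' @export
fit_mirpls <- function(X, y, ncomp, n_knots, tol = 1e-6, max_iter = 30L) {
  X <- validate_matrix(X, "X")
  y <- drop(as_numeric_matrix(y, "y"))
  if (!is.vector(y) || length(y) != nrow(X)) {
    mirpls_error("`y` must be a single response vector with length nrow(X)",
                 "mirpls_shape_error")
  }
  if (stats::sd(y) == 0) {
    mirpls_error("`y` is constant; nothing to model", "mirpls_validation_error")
  }
  A_max <- min(nrow(X) - 1L, ncol(X))
  if (length(ncomp) != 1L || ncomp < 1 || ncomp > A_max || ncomp != round(ncomp)) {
    mirpls_error(sprintf("`ncomp` must be an integer in [1, %d]", A_max),
                 "mirpls_parameter_error")
  }
  stopifnot(length(n_knots) == 1L, n_knots >= 0, n_knots == round(n_knots))
  A <- as.integer(ncomp); J <- as.integer(n_knots)

  sx <- autoscale(X)
  sy <- autoscale(matrix(y, ncol = 1))
  Xh <- sx$scaled
  yh <- drop(sy$scaled)
  N <- nrow(Xh); M <- ncol(Xh)
  normX0 <- sqrt(sum(Xh^2))

  components <- vector("list", A)
  trace_rows <- matrix(0, A * max_iter, 5,
                       dimnames = list(NULL, c("component", "iteration",
                                               "weight_correction_norm",
                                               "score_change", "error_norm")))
  n_rows <- 0L
  notes <- character(0)
  A_eff <- 0L

  for (h in seq_len(A)) {
    u <- yh
    if (stats::sd(u) == 0 || l2norm(u) < 1e-12 * sqrt(N)) {
      notes <- c(notes, sprintf("component %d: response residual exhausted", h))
      break
    }
    w <- normalize(drop(crossprod(Xh, u)) / sum(u^2))
    t <- drop(Xh %*% w)
    if (l2norm(t) < 1e-12 * max(normX0, 1)) {
      notes <- c(notes, sprintf("component %d: score norm collapsed", h))
      break
    }
    spl <- NULL
    q <- 1
    converged <- FALSE
    iters <- 0L
    for (i in seq_len(max_iter)) {
      iters <- i
      spl <- fit_monotone_spline(t, u, J)
      u_hat <- eval_spline(spl, t)
      qt <- sum(u_hat * yh)
      q <- if (qt < 0) -1 else 1
      u <- yh * q
      t_hat <- invert_spline(spl, u)
      upd <- update_weights_core(Xh, w, t, t_hat)
      w_new <- upd$w_new
      t_new <- drop(Xh %*% w_new)
      change <- l2norm(t_new - t) / l2norm(t)
      n_rows <- n_rows + 1L
      trace_rows[n_rows, ] <- c(h, i, l2norm(upd$delta_w), change,
                                l2norm(t_hat - t))
      w <- w_new
      t <- t_new
      if (change < tol) { converged <- TRUE; break }
    }
    p <- drop(crossprod(Xh, t)) / sum(t * t)
    spl_final <- fit_monotone_spline(t, u, J)
    u_hat_new <- eval_spline(spl_final, t)
    if (length(spl_final$notes)) {
      notes <- c(notes, sprintf("component %d: %s", h,
                                paste(spl_final$notes, collapse = "; ")))
    }
    components[[h]] <- list(
      w = w, p = p, q = q,
      spline = spl_final,
      t_train = t, u_train = u,
      converged = converged, iterations = iters
    )
    Xh <- Xh - tcrossprod(t, p)
    yh <- yh - u_hat_new * q
    A_eff <- h
  }

  if (A_eff == 0L) {
    mirpls_error("no MIR-PLS component could be extracted", "mirpls_rank_error")
  }
  components <- components[seq_len(A_eff)]
  trace_df <- as.data.frame(trace_rows[seq_len(n_rows), , drop = FALSE])
  trace_df$converged <- vapply(trace_df$component, function(h)
    components[[h]]$converged, logical(1))

  model <- structure(list(
    components = components,
    n_components = A_eff,
    n_knots = J,
    tol = tol,
    max_iter = as.integer(max_iter),
    x_scaler = sx$scaler,
    y_scaler = sy$scaler,
    x_residual = Xh,
    trace = trace_df,
    notes = notes
  ), class = "mirpls_model")
  model$fitted <- drop(predict(model, X))
  model
}

#' Predict from a fitted MIR-PLS model
#'
#' New samples are autoscaled with the training scaler, then passed through
#' the components sequentially, mirroring training: per component, scores
#' `t* = X* w`, spline predictions `phi(t*)` accumulate into the scaled
#' response, and the predictor residual is deflated by `t* p'` before the
#' next component. The result is back-transformed with the response scaler.
#'
#' @param object a `mirpls_model`.
#' @param newdata matrix with the training number of columns.
#' @param ncomp optionally use only the first `ncomp` components.
#' @param ... unused.
#' @return Numeric vector of predictions on the original response scale.
#' @export
predict.mirpls_model <- function(object, newdata, ncomp = NULL, ...) {
  newdata <- as_numeric_matrix(newdata, "newdata")
  if (ncol(newdata) != length(object$x_scaler$means)) {
    mirpls_error(sprintf("`newdata` has %d columns, model expects %d",
                         ncol(newdata), length(object$x_scaler$means)),
                 "mirpls_shape_error")
  }
  A <- if (is.null(ncomp)) object$n_components else min(ncomp, object$n_components)
  Xs <- autoscale(newdata, scaler = object$x_scaler)$scaled
  yhat_s <- numeric(nrow(Xs))
  for (h in seq_len(A)) {
    cmp <- object$components[[h]]
    t_star <- drop(Xs %*% cmp$w)
    yhat_s <- yhat_s + eval_spline(cmp$spline, t_star) * cmp$q
    Xs <- Xs - tcrossprod(t_star, cmp$p)
  }
  drop(unscale(yhat_s, object$y_scaler))
}

#' @export
fitted.mirpls_model <- function(object, ...) object$fitted

#' Fit independent MIR-PLS models for a multi-response matrix
#'
#' One single-response model is fitted per column of `Y` (no shared
#' deflation), matching how multi-endpoint dose-effect responses are reported
#' separately. Hyperparameters may be scalars (recycled) or per-column
#' vectors.
#'
#' @param X predictor matrix.
#' @param Y response matrix with `K >= 2` columns.
#' @param ncomp,n_knots scalar or length-K vectors.
#' @param ... passed to [fit_mirpls()].
#' @return List of `mirpls_model`, one per response column, named by the
#'   column names of `Y` when present.
#' @export
fit_mirpls_multiresponse <- function(X, Y, ncomp, n_knots, ...) {
  Y <- as_numeric_matrix(Y, "Y")
  K <- ncol(Y)
  if (K < 2L) {
    mirpls_error("`Y` must have at least 2 columns; use fit_mirpls() for K = 1",
                 "mirpls_shape_error")
  }
  ncomp <- rep_len(ncomp, K)
  n_knots <- rep_len(n_knots, K)
  models <- vector("list", K)
  for (k in seq_len(K)) {
    models[[k]] <- tryCatch(
      fit_mirpls(X, Y[, k], ncomp = ncomp[k], n_knots = n_knots[k], ...),
      error = function(e) {
        mirpls_error(sprintf("response column %d: %s", k, conditionMessage(e)),
                     class(e)[1])
      })
  }
  names(models) <- colnames(Y)
  models
}

#' @export
print.mirpls_model <- function(x, ...) {
  cat(sprintf("MIR-PLS model: %d component(s), %d interior knot(s), %d predictors\n",
              x$n_components, x$n_knots, length(x$x_scaler$means)))
  conv <- vapply(x$components, `[[`, logical(1), "converged")
  its <- vapply(x$components, `[[`, integer(1), "iterations")
  cat(sprintf("Inner iterations per component: %s (converged: %s)\n",
              paste(its, collapse = ", "), paste(conv, collapse = ", ")))
  if (length(x$notes)) cat("Notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
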