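#' Column-wise autoscaling (zero mean, unit variance)
#'
#' Centers every column and divides by its sample standard deviation
#' (divisor `N - 1`, the chemometrics convention). Constant columns are
#' centered only: their divisor is set to 1 and they are flagged in
#' `zero_variance_mask`, so constant predictors in tiny designed experiments
#' do not produce divisions by zero.
#'
#' @param X numeric matrix (rows = samples, columns = variables).
#' @param scaler optional scaler returned by a previous call; when supplied,
#'   `X` is transformed with the stored means/standard deviations instead of
#'   refitting (used to scale test data with training statistics).
#' @return A list with `scaled` (the transformed matrix) and `scaler`, an
#'   object of class `mirpls_scaler` holding `means`, `stds` and
#'   `zero_variance_mask`.
#' @examples
#' s <- autoscale(matrix(c(1, 2, 3, 5, 5, 5), ncol = 2))
#' colMeans(s$scaled)
#' s$scaler$zero_variance_mask
#' @export
autoscale <- function(X, scaler = NULL) {
  # fitting the scaler needs >= 2 rows; applying a fitted one works row-wise
  X <- validate_matrix(X, "X", min_rows = if (is.null(scaler)) 2L else 1L)
  if (is.null(scaler)) {
    means <- colMeans(X)
    stds <- apply(X, 2, stats::sd)
    zero_var <- !is.finite(stds) | stds <= 0
    stds[zero_var] <- 1
    scaler <- structure(
      list(means = means, stds = stds, zero_variance_mask = zero_var),
      class = "mirpls_scaler"
    )
  } else {
    stopifnot(inherits(scaler, "mirpls_scaler"))
    if (ncol(X) != length(scaler$means)) {
      mirpls_error(sprintf("`X` has %d columns but the scaler was fitted on %d",
                           ncol(X), length(scaler$means)),
                   "mirpls_shape_error")
    }
  }
  scaled <- sweep(sweep(X, 2, scaler$means, "-"), 2, scaler$stds, "/")
  list(scaled = scaled, scaler = scaler)
}

#' Invert an autoscaling transform
#'
#' @param Xs scaled matrix (or vector, interpreted as a single column when the
#'   scaler has one variable).
#' @param scaler a `mirpls_scaler`.
#' @return Matrix on the original scale.
#' @export
unscale <- function(Xs, scaler) {
  stopifnot(inherits(scaler, "mirpls_scaler"))
  if (is.vector(Xs)) Xs <- matrix(Xs, ncol = length(scaler$means))
  sweep(sweep(Xs, 2, scaler$stds, "*"), 2, scaler$means, "+")
}
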