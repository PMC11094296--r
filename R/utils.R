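# Internal helpers: input validation, condition constructors, seeded RNG scope.

mirpls_error <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "mirpls_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

#' @noRd
as_numeric_matrix <- function(x, arg = "X") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1)
  if (!is.matrix(x) || !is.numeric(x)) {
    mirpls_error(sprintf("`%s` must be a numeric matrix", arg), "mirpls_validation_error")
  }
  x
}

# Validates the basic data-matrix contract: finite entries, N >= 2, M >= 1.
# Reports the first offending cell by row/column so tiny hand-built datasets
# are easy to debug.
validate_matrix <- function(x, arg = "X", min_rows = 2L) {
  x <- as_numeric_matrix(x, arg)
  if (nrow(x) < min_rows || ncol(x) < 1L) {
    mirpls_error(sprintf("`%s` must have at least %d rows and 1 column (got %d x %d)",
                         arg, min_rows, nrow(x), ncol(x)),
                 "mirpls_validation_error")
  }
  bad <- which(!is.finite(x))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(x))
    mirpls_error(sprintf("`%s` contains a non-finite value at row %d, column %d",
                         arg, ij[1L], ij[2L]),
                 "mirpls_validation_error")
  }
  x
}

l2norm <- function(v) sqrt(sum(v^2))

normalize <- function(v) {
  nv <- l2norm(v)
  if (nv == 0) v else v / nv
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
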