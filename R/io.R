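# Delimited-text data input/output and JSON model (de)serialization.
# Numeric output uses 17 significant digits so read(write(X)) is bit-stable.

MODEL_SCHEMA_VERSION <- "1.0"

#' Read a numeric CSV table
#'
#' Expects a comma-separated file with a header row and an all-numeric body
#' (rows = samples, columns = variables). Missing or non-numeric cells raise
#' an error naming the offending row and column.
#'
#' @param path file path.
#' @return Numeric matrix with column names from the header.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) {
    mirpls_error(sprintf("file not found: %s", path), "mirpls_io_error")
  }
  df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  if (nrow(df) == 0L || ncol(df) == 0L) {
    mirpls_error(sprintf("%s: no data rows (header-only or empty file)", path),
                 "mirpls_parse_error")
  }
  out <- matrix(NA_real_, nrow(df), ncol(df),
                dimnames = list(NULL, names(df)))
  for (j in seq_len(ncol(df))) {
    vals <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(vals))
    if (length(bad)) {
      mirpls_error(sprintf("%s: non-numeric or missing value '%s' at row %d, column '%s'",
                           path, df[[j]][bad[1L]], bad[1L], names(df)[j]),
                   "mirpls_parse_error")
    }
    out[, j] <- vals
  }
  out
}

#' Write a numeric table as CSV
#'
#' Full-precision output (17 significant digits): reading the file back
#' reproduces the matrix exactly.
#'
#' @param X numeric matrix or vector.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_table <- function(X, path) {
  X <- as_numeric_matrix(X, "X")
  cn <- colnames(X)
  if (is.null(cn)) cn <- sprintf("V%d", seq_len(ncol(X)))
  body <- apply(X, 1:2, function(v) sprintf("%.17g", v))
  body <- matrix(body, nrow(X), ncol(X))
  lines <- c(paste(cn, collapse = ","),
             apply(body, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

spline_to_list <- function(sp) {
  list(interior_knots = sp$knots$interior,
       boundary = sp$knots$boundary,
       coefficients = sp$coefficients,
       direction = sp$direction,
       derivative_floor = sp$derivative_floor,
       fitted_domain = sp$fitted_domain,
       sse = sp$sse,
       notes = sp$notes)
}

spline_from_list <- function(l) {
  num <- function(x, what) {
    x <- unlist(x)
    if (!is.numeric(x)) {
      mirpls_error(sprintf("model file: field '%s' is not numeric", what),
                   "mirpls_parse_error")
    }
    as.numeric(x)
  }
  kv <- structure(list(interior = num(l$interior_knots %||% numeric(0), "interior_knots"),
                       boundary = num(l$boundary, "boundary")),
                  class = "knot_vector")
  aug <- aug_knots(kv)
  beta <- num(l$coefficients, "coefficients")
  structure(list(
    knots = kv,
    coefficients = beta,
    direction = num(l$direction, "direction"),
    derivative_floor = num(l$derivative_floor, "derivative_floor"),
    fitted_domain = num(l$fitted_domain, "fitted_domain"),
    s_domain = kv$boundary,
    aug = aug,
    boundary_values = drop(bspline_design(aug, kv$boundary) %*% beta),
    boundary_slopes = pmax(drop(bspline_design(aug, kv$boundary, deriv = 1L) %*% beta), 0),
    fitted = NULL,
    sse = num(l$sse %||% NA_real_, "sse"),
    notes = as.character(unlist(l$notes %||% character(0)))
  ), class = "monotone_spline")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scaler_to_list <- function(s) {
  list(means = s$means, stds = s$stds, zero_variance_mask = s$zero_variance_mask)
}

scaler_from_list <- function(l) {
  structure(list(means = as.numeric(unlist(l$means)),
                 stds = as.numeric(unlist(l$stds)),
                 zero_variance_mask = as.logical(unlist(l$zero_variance_mask))),
            class = "mirpls_scaler")
}

#' Save a fitted MIR-PLS model as structured text (JSON)
#'
#' Full-precision decimals; includes a schema version that [load_model()]
#' checks. The round trip preserves predictions to machine precision.
#'
#' @param model a `mirpls_model`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mirpls_model"))
  payload <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    model_type = "mirpls",
    n_components = model$n_components,
    n_knots = model$n_knots,
    tol = model$tol,
    max_iter = model$max_iter,
    x_scaler = scaler_to_list(model$x_scaler),
    y_scaler = scaler_to_list(model$y_scaler),
    components = lapply(model$components, function(cmp) {
      list(w = cmp$w, p = cmp$p, q = cmp$q,
           spline = spline_to_list(cmp$spline),
           converged = cmp$converged, iterations = cmp$iterations)
    }),
    notes = model$notes
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a MIR-PLS model saved by [save_model()]
#'
#' @param path path to the JSON model file.
#' @return A `mirpls_model` usable with `predict()`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    mirpls_error(sprintf("file not found: %s", path), "mirpls_io_error")
  }
  payload <- tryCatch(jsonlite::read_json(path),
                      error = function(e)
                        mirpls_error(sprintf("model file unreadable: %s", conditionMessage(e)),
                                     "mirpls_parse_error"))
  if (is.null(payload$schema_version) || payload$schema_version != MODEL_SCHEMA_VERSION) {
    mirpls_error(sprintf("model schema version mismatch: file has '%s', expected '%s'",
                         payload$schema_version %||% "<missing>", MODEL_SCHEMA_VERSION),
                 "mirpls_version_error")
  }
  num <- function(x, what) {
    x <- unlist(x)
    if (is.null(x) || !is.numeric(x)) {
      mirpls_error(sprintf("model file: field '%s' missing or not numeric", what),
                   "mirpls_parse_error")
    }
    as.numeric(x)
  }
  components <- lapply(payload$components, function(cl) {
    list(w = num(cl$w, "w"), p = num(cl$p, "p"), q = num(cl$q, "q"),
         spline = spline_from_list(cl$spline),
         t_train = NULL, u_train = NULL,
         converged = isTRUE(cl$converged),
         iterations = as.integer(cl$iterations %||% NA_integer_))
  })
  structure(list(
    components = components,
    n_components = as.integer(payload$n_components),
    n_knots = as.integer(payload$n_knots),
    tol = as.numeric(payload$tol),
    max_iter = as.integer(payload$max_iter),
    x_scaler = scaler_from_list(payload$x_scaler),
    y_scaler = scaler_from_list(payload$y_scaler),
    trace = NULL,
    notes = as.character(unlist(payload$notes %||% character(0)))
  ), class = "mirpls_model")
}
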