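# Synthetic collinear, monotone-nonlinear calibration data.
#
# The generator emulates the two data regimes the estimator targets:
# designed dose-effect experiments (a dozen samples, eight blood-concentration
# predictors, one to three pharmacological endpoints) and NIR spectra
# (hundreds of smooth, highly correlated wavelength channels). Predictors are
# built from a low-rank latent structure plus optional noise, so the
# multicollinearity that motivates latent-variable regression is present by
# construction, and the response passes a known monotone function of a known
# latent score, so ground truth is available for every test.

INNER_FUNCTIONS <- c("linear", "tanh", "exponential", "cubic", "logistic")

# Monotone link applied to the standardized latent score. Each is
# parameterized to span its curvature over roughly +/- 2 sd of the realized
# scores, so the nonlinearity is actually exercised.
inner_function_g <- function(name) {
  switch(name,
    linear      = function(z) z,
    tanh        = function(z) tanh(2 * z),
    exponential = function(z) exp(z) / exp(1),
    cubic       = function(z) z^3 / 4,
    logistic    = function(z) 1 / (1 + exp(-3 * z)),
    mirpls_error(sprintf("unknown inner function '%s'", name), "mirpls_parameter_error")
  )
}

#' Specification for a synthetic dataset
#'
#' Generation is a pure function of the spec: the same spec always yields the
#' same data. The single seed expands into separate sub-streams for the
#' latent structure, X-noise, and y-noise, so changing a noise level does not
#' reshuffle the structure.
#'
#' @param N,M samples and predictors.
#' @param latent_rank rank r of the predictor structure, `r <= min(N, M)`;
#'   with `noise_sd_x = 0` the predictor matrix has exactly rank r, giving
#'   perfect multicollinearity.
#' @param inner_function one of `"linear"`, `"tanh"`, `"exponential"`,
#'   `"cubic"`, `"logistic"` — the monotone link from latent score to
#'   response.
#' @param noise_sd_x,noise_sd_y noise standard deviations (X entrywise, y
#'   additive).
#' @param seed integer seed.
#' @param true_weights optional unit vector of length M defining the latent
#'   score; generated when omitted.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(N, M, latent_rank, inner_function = "tanh",
                           noise_sd_x = 0.05, noise_sd_y = 0.1, seed = 1L,
                           true_weights = NULL) {
  stopifnot(N >= 2, M >= 1, latent_rank >= 1)
  if (latent_rank > min(N, M)) {
    mirpls_error("`latent_rank` must not exceed min(N, M)", "mirpls_parameter_error")
  }
  inner_function <- match.arg(inner_function, INNER_FUNCTIONS)
  stopifnot(noise_sd_x >= 0, noise_sd_y >= 0)
  if (!is.null(true_weights)) {
    stopifnot(length(true_weights) == M)
    true_weights <- normalize(true_weights)
  }
  structure(list(N = as.integer(N), M = as.integer(M),
                 latent_rank = as.integer(latent_rank),
                 inner_function = inner_function,
                 noise_sd_x = noise_sd_x, noise_sd_y = noise_sd_y,
                 seed = as.integer(seed), true_weights = true_weights),
            class = "synthetic_spec")
}

#' Generate a synthetic dataset from a spec
#'
#' `X = L V' + noise_sd_x * E` with `L` (N x r) and `V` (M x r) standard
#' normal, so `X` carries rank-r structure plus isotropic noise. The latent
#' score is `t_true = X w_true`; the noiseless response is
#' `u_true = g((t_true - mean) / sd)` for the chosen monotone `g`; and
#' `y = u_true + noise_sd_y * eps`.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `X`, `y`, and `truth` (a list holding `t_true`,
#'   `u_true`, `w_true`, `L`, `V`).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  structure_draw <- with_seed(spec$seed, {
    L <- matrix(stats::rnorm(spec$N * spec$latent_rank), spec$N, spec$latent_rank)
    V <- matrix(stats::rnorm(spec$M * spec$latent_rank), spec$M, spec$latent_rank)
    w <- if (is.null(spec$true_weights)) normalize(stats::rnorm(spec$M)) else spec$true_weights
    list(L = L, V = V, w = w)
  })
  E <- with_seed(spec$seed + 1L, matrix(stats::rnorm(spec$N * spec$M), spec$N, spec$M))
  eps <- with_seed(spec$seed + 2L, stats::rnorm(spec$N))
  X <- tcrossprod(structure_draw$L, structure_draw$V) + spec$noise_sd_x * E
  colnames(X) <- sprintf("x%d", seq_len(spec$M))
  t_true <- drop(X %*% structure_draw$w)
  z <- (t_true - mean(t_true)) / max(stats::sd(t_true), 1e-12)
  u_true <- inner_function_g(spec$inner_function)(z)
  y <- u_true + spec$noise_sd_y * eps
  list(X = X, y = y,
       truth = list(t_true = t_true, u_true = u_true, w_true = structure_draw$w,
                    L = structure_draw$L, V = structure_draw$V))
}

#' Dose-effect-shaped synthetic fixture
#'
#' Shapes follow the motivating designed experiments: `K = 1` gives
#' `N = 12` samples, `K = 2` or `K = 3` give `N = 13`, always with `M = 8`
#' predictor columns (blood-concentration analogues) of rank-3 structure.
#' Each response column uses a different monotone inner function.
#'
#' @param seed integer seed.
#' @param K number of response columns (1, 2 or 3).
#' @return List with `X` (N x 8), `Y` (N x K), and per-column `truth`.
#' @export
fixture_cm_like <- function(seed = 1L, K = 1L) {
  stopifnot(K %in% 1:3)
  N <- if (K == 1L) 12L else 13L
  links <- c("tanh", "exponential", "logistic")[seq_len(K)]
  cols <- lapply(seq_len(K), function(k) {
    generate_synthetic(synthetic_spec(
      N = N, M = 8L, latent_rank = 3L, inner_function = links[k],
      noise_sd_x = if (k == 1L) 0.05 else 0, noise_sd_y = 0.1,
      seed = seed + (k - 1L) * 1000L))
  })
  # one shared X (the first column's draw); responses re-derived on it so all
  # K endpoints observe the same experiment
  X <- cols[[1L]]$X
  truth <- vector("list", K)
  Y <- matrix(0, N, K)
  for (k in seq_len(K)) {
    w <- cols[[k]]$truth$w_true
    t_true <- drop(X %*% w)
    z <- (t_true - mean(t_true)) / max(stats::sd(t_true), 1e-12)
    u_true <- inner_function_g(links[k])(z)
    eps <- with_seed(seed + (k - 1L) * 1000L + 2L, stats::rnorm(N))
    Y[, k] <- u_true + 0.1 * eps
    truth[[k]] <- list(t_true = t_true, u_true = u_true, w_true = w,
                       inner_function = links[k])
  }
  colnames(Y) <- sprintf("y%d", seq_len(K))
  list(X = X, Y = Y, truth = truth)
}

#' NIR-spectra-shaped synthetic fixture
#'
#' Smooth, highly correlated predictor columns built from Gaussian-bump
#' latent factors over the wavelength index, emulating transmittance spectra.
#' `size = "small"` gives N = 80 samples of M = 576 channels (many more
#' variables than samples); `size = "large"` gives N = 415 samples of M = 100
#' channels.
#'
#' @param seed integer seed.
#' @param size `"small"` or `"large"`.
#' @param noise_sd_x,noise_sd_y noise levels (defaults small, spectra are
#'   smooth).
#' @return List with `X`, `y`, `truth` as in [generate_synthetic()].
#' @export
fixture_nir_like <- function(seed = 1L, size = c("small", "large"),
                             noise_sd_x = 0.01, noise_sd_y = 0.1) {
  size <- match.arg(size)
  N <- if (size == "small") 80L else 415L
  M <- if (size == "small") 576L else 100L
  r <- 6L
  wl <- seq(0, 1, length.out = M)
  draw <- with_seed(seed, {
    centers <- stats::runif(r)
    widths <- stats::runif(r, 0.15, 0.35)
    amps <- stats::rnorm(r, 1, 0.2)
    L <- matrix(stats::rnorm(N * r), N, r)
    w_mix <- normalize(stats::rnorm(r))
    list(centers = centers, widths = widths, amps = amps, L = L, w_mix = w_mix)
  })
  V <- vapply(seq_len(r), function(j)
    draw$amps[j] * exp(-(wl - draw$centers[j])^2 / (2 * draw$widths[j]^2)),
    numeric(M))
  E <- with_seed(seed + 1L, matrix(stats::rnorm(N * M), N, M))
  eps <- with_seed(seed + 2L, stats::rnorm(N))
  X <- tcrossprod(draw$L, V) + noise_sd_x * E
  colnames(X) <- sprintf("wl%03d", seq_len(M))
  # latent score: a fixed mixture of the factor activations, monotone link
  t_true <- drop(draw$L %*% draw$w_mix)
  z <- (t_true - mean(t_true)) / max(stats::sd(t_true), 1e-12)
  u_true <- tanh(2 * z)
  y <- u_true + noise_sd_y * eps
  list(X = X, y = y,
       truth = list(t_true = t_true, u_true = u_true, V = V, L = draw$L))
}
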