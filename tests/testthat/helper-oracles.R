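# Independent oracles used across the suite. Each deliberately takes a
# different computational route than the package implementation it checks.

# PLS1 regression coefficients via the Krylov-subspace characterization:
# beta_A = K (K' X'X K)^{-1} K' X'y with K = [s, Gs, ..., G^{A-1}s],
# s = X'y, G = X'X (orthonormalized for stability). Mathematically identical
# to A-component NIPALS PLS1 on centered data, computed without any
# deflation or score/loading recursion.
oracle_pls1_coef <- function(X, y, A) {
  s <- crossprod(X, y)
  G <- crossprod(X)
  K <- matrix(0, ncol(X), A)
  v <- s
  for (a in seq_len(A)) {
    K[, a] <- v
    v <- G %*% v
  }
  K <- qr.Q(qr(K))
  M <- crossprod(K, G %*% K)
  drop(K %*% solve(M, crossprod(K, s)))
}

# Generic inequality-constrained least-squares fit of a monotone cubic
# spline: full B-spline basis on the same quantile knots, derivative >= 0
# imposed on a dense grid, solved by mgcv::pcls (a quadratic-programming
# routine unrelated to the package's Lawson-Hanson solver). Returns the SSE.
oracle_monotone_sse <- function(t, u, J, n_grid = 4096L) {
  dir_cor <- suppressWarnings(stats::cor(t, u))
  dir <- if (is.finite(dir_cor) && dir_cor < 0) -1 else 1
  s <- dir * t
  qs <- if (J > 0) stats::quantile(s, probs = seq_len(J) / (J + 1),
                                   type = 7, names = FALSE) else numeric(0)
  lo <- min(s); hi <- max(s)
  qs <- unique(qs[qs > lo & qs < hi])
  aug <- c(rep(lo, 4), qs, rep(hi, 4))
  B <- splines::splineDesign(aug, s, ord = 4)
  g <- seq(lo, hi, length.out = n_grid)
  D <- splines::splineDesign(aug, g, ord = 4, derivs = rep(1L, n_grid))
  L <- ncol(B)
  xi <- vapply(seq_len(L), function(j) mean(aug[(j + 1):(j + 3)]), numeric(1))
  slope <- max(stats::cov(s, u) / stats::var(s), 1e-8)
  p_init <- mean(u) + slope * (xi - mean(s))
  M <- list(y = u, w = rep(1, length(u)), X = B, C = matrix(0, 0, L),
            S = list(), off = array(0, 0), sp = array(0, 0),
            p = p_init, Ain = D, bin = rep(0, n_grid))
  beta <- mgcv::pcls(M)
  sum((u - drop(B %*% beta))^2)
}

# Exact two-sided signed-rank p-value by brute-force enumeration over all
# 2^n sign assignments (n <= ~16). Same zero-drop and midrank conventions.
oracle_wilcoxon_p <- function(errors_a, errors_b) {
  d <- abs(errors_a) - abs(errors_b)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1), function(mask) {
    signs <- as.integer(intToBits(mask))[seq_len(n)]
    sum(r[signs == 1])
  }, numeric(1))
  p_le <- mean(vs <= v + 1e-9)
  p_ge <- mean(vs >= v - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
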