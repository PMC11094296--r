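# Inequality-constrained least squares via the Lawson-Hanson route:
# NNLS -> LDP -> general problem  min ||B beta - u||^2  s.t.  D beta >= 0.
# Problem sizes here are tiny (<= ~10 coefficients, a few hundred constraint
# rows), so a careful pure-R active-set implementation is appropriate.

# Least squares by C-level pivoted QR; rank-deficient directions get zero.
ls_coef <- function(A, b) {
  z <- .lm.fit(A, b)
  cf <- numeric(ncol(A))
  cf[z$pivot] <- z$coefficients
  cf[is.na(cf)] <- 0
  cf
}

# Nonnegative least squares, Lawson & Hanson (1974) active-set algorithm.
# Returns the coefficient vector x >= 0 minimizing ||A x - b||. Degenerate
# (near-duplicate) columns are common in our constraint systems, so the
# inner feasibility loop is capped and near-zero solutions are accepted and
# clamped rather than cycled on.
nnls_solve <- function(A, b, max_outer = NULL) {
  p <- ncol(A)
  if (is.null(max_outer)) max_outer <- 3L * min(p, nrow(A)) + 20L
  x <- numeric(p)
  passive <- logical(p)
  resid <- b
  w <- drop(crossprod(A, resid))
  tol <- 1e-12 * max(abs(w), 1)
  outer <- 0L
  while (any(!passive) && max(w[!passive]) > tol && outer < max_outer) {
    outer <- outer + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    inner <- 0L
    repeat {
      inner <- inner + 1L
      s <- numeric(p)
      s[passive] <- ls_coef(A[, passive, drop = FALSE], b)
      smax <- max(abs(s))
      if (all(s[passive] > -1e-12 * max(smax, 1)) || inner > 3L * p + 10L) {
        x <- pmax(s, 0)
        break
      }
      move <- passive & (s <= 0)
      ratios <- x[move] / (x[move] - s[move])
      ratios[!is.finite(ratios)] <- Inf       # 0/0: index carries no step limit
      alpha <- min(ratios)
      if (!is.finite(alpha)) alpha <- 0
      x <- x + alpha * (s - x)
      passive[passive] <- x[passive] > .Machine$double.eps^0.75 * max(abs(x), 1e-300)
      x[!passive] <- 0
      if (!any(passive)) {
        x <- numeric(p)
        break
      }
    }
    resid <- b - drop(A %*% x)
    w <- drop(crossprod(A, resid))
  }
  x
}

# Least distance programming: min ||x|| s.t. G x >= h, solved through one
# NNLS problem (Lawson & Hanson, ch. 23). Returns NULL when infeasible.
ldp_solve <- function(G, h, max_outer = NULL) {
  n <- ncol(G)
  E <- rbind(t(G), h)
  f <- c(numeric(n), 1)
  u <- nnls_solve(E, f, max_outer = max_outer)
  r <- drop(E %*% u) - f
  nr <- l2norm(r)
  if (nr < 1e-10) return(NULL)
  -r[seq_len(n)] / r[n + 1L]
}

# min ||B beta - u||^2 subject to D beta >= 0, B assumed full column rank.
# Reduced to LDP on the QR-rotated coordinates. The NNLS iteration caps are
# tight for speed (degenerate constraint sets cycle); if the recovered point
# measurably violates the constraints, the LDP is re-run with generous caps.
constrained_ls <- function(B, u, D) {
  qrB <- qr(B)
  if (qrB$rank < ncol(B)) {
    mirpls_error("design matrix is rank deficient in constrained least squares",
                 "mirpls_rank_error")
  }
  R <- qr.R(qrB)
  c0 <- qr.qty(qrB, u)[seq_len(ncol(B))]
  beta_ols <- backsolve(R, c0)
  viol <- drop(D %*% beta_ols)
  if (all(viol >= 0)) return(beta_ols)   # unconstrained optimum already feasible
  Grot <- t(backsolve(R, t(D), transpose = TRUE))   # D %*% R^{-1}
  feas_tol <- 1e-11 * max(1, max(abs(viol)))
  beta <- NULL
  for (cap in list(NULL, 40L * min(nrow(Grot) + 1L, ncol(Grot)) + 200L)) {
    gamma <- ldp_solve(Grot, -viol, max_outer = cap)
    if (is.null(gamma)) {
      mirpls_error("constrained least squares: constraint system infeasible",
                   "mirpls_solver_error")
    }
    beta <- backsolve(R, gamma + c0)
    if (min(drop(D %*% beta)) >= -feas_tol) break
  }
  beta
}
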