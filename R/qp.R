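#' Primal-dual interior-point solver for the simplex-constrained QP
#'
#' Minimizes `w' H w` subject to `sum(w) = 1` and `0 <= w <= 1` for a
#' symmetric positive-semidefinite `H`. This is the Newton-step solver used
#' for the per-kernel lag-weight program: at each iteration the KKT system is
#' reduced by block elimination of the bound multipliers, a single symmetric
#' `n x n` solve yields the primal step, and a fraction-to-the-boundary rule
#' keeps all iterates strictly interior. Convergence is declared when the
#' complementarity measure (duality gap) and the primal/dual residuals fall
#' below `tol` relative to the problem scale.
#'
#' @param H symmetric PSD matrix (`n x n`).
#' @param tol duality-gap tolerance (relative to the problem scale).
#' @param max_iter maximum number of interior-point iterations.
#' @param sigma centering parameter in `(0, 1)`.
#' @return List with `w` (solution), `converged` (logical), `iterations`,
#'   `gap` (final complementarity measure) and `kkt_residual` (max norm of
#'   the stationarity + feasibility residuals).
#' @keywords internal
qp_simplex_pdip <- function(H, tol = 1e-10, max_iter = 200, sigma = 0.1) {
  n <- nrow(H)
  scale <- max(1, max(abs(H)))
  w <- rep(1 / n, n)
  lam <- rep(1, n)   # multipliers for w >= 0
  mu <- rep(1, n)    # multipliers for w <= 1
  y <- 0             # multiplier for sum(w) = 1
  ones <- rep(1, n)
  for (it in seq_len(max_iter)) {
    g <- 2 * drop(H %*% w)
    r_dual <- g + y * ones - lam + mu
    r_prim <- sum(w) - 1
    gap <- (sum(lam * w) + sum(mu * (1 - w))) / (2 * n)
    if (gap < tol * scale && abs(r_prim) < tol &&
        max(abs(r_dual)) < tol * scale) {
      return(list(w = w, converged = TRUE, iterations = it, gap = gap,
                  kkt_residual = max(abs(r_dual), abs(r_prim))))
    }
    shift <- sigma * gap
    M <- 2 * H + diag(lam / w + mu / (1 - w), n)
    rhs <- -g - y * ones + shift / w - shift / (1 - w)
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) {
      ch <- chol(M + diag(1e-12 * scale, n))
    }
    Minv_r <- backsolve(ch, forwardsolve(t(ch), rhs))
    Minv_1 <- backsolve(ch, forwardsolve(t(ch), ones))
    dy <- (sum(Minv_r) + r_prim) / sum(Minv_1)
    dw <- Minv_r - dy * Minv_1
    dlam <- -lam + shift / w - (lam / w) * dw
    dmu <- -mu + shift / (1 - w) + (mu / (1 - w)) * dw
    # fraction-to-the-boundary step keeping w in (0, 1), lam, mu > 0
    step <- function(v, dv) {
      neg <- dv < 0
      if (!any(neg)) return(1)
      min(1, 0.99 * min(-v[neg] / dv[neg]))
    }
    a <- min(step(w, dw), step(1 - w, -dw), step(lam, dlam), step(mu, dmu))
    w <- w + a * dw
    lam <- lam + a * dlam
    mu <- mu + a * dmu
    y <- y + a * dy
  }
  g <- 2 * drop(H %*% w)
  list(w = w, converged = FALSE, iterations = max_iter,
       gap = (sum(lam * w) + sum(mu * (1 - w))) / (2 * n),
       kkt_residual = max(abs(g + y * ones - lam + mu), abs(sum(w) - 1)))
}

#' Generic convex-QP fallback via quadprog
#'
#' Same problem as [qp_simplex_pdip()], solved with the active-set method of
#' [quadprog::solve.QP()]. Used only when the interior-point iteration fails
#' to converge, and as an independent cross-check in the test suite.
#'
#' @inheritParams qp_simplex_pdip
#' @return Numeric solution vector.
#' @keywords internal
qp_simplex_quadprog <- function(H) {
  n <- nrow(H)
  Dmat <- 2 * H + diag(1e-9 * max(1, sum(diag(H))) / n, n)
  Amat <- cbind(rep(1, n), diag(n), -diag(n))
  bvec <- c(1, rep(0, n), rep(-1, n))
  quadprog::solve.QP(Dmat, rep(0, n), Amat, bvec, meq = 1)$solution
}
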