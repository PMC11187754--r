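# Generic two-point BVP collocation core.
#
# Discretization: 3-stage Lobatto IIIA in its condensed ("Simpson with
# Hermite midpoint") form, the classical bvp4c scheme.  For each interval
# [eta_i, eta_{i+1}] with step h:
#
#   u_m   = (u_i + u_{i+1})/2 + (h/8) (F_i - F_{i+1})
#   res_i = u_{i+1} - u_i - (h/6) (F_i + 4 F(eta_m, u_m) + F_{i+1})
#
# which is 4th-order accurate at the nodes.  The Newton matrix is block
# bidiagonal (2 dense n x n blocks per interval) and is assembled as one
# sparse matrix; steps are damped by a simple Armijo backtracking line
# search.  Everything is deterministic.

#' Graded mesh for a semi-infinite boundary layer
#'
#' sinh-graded abscissae on `[0, eta_inf]`: node density at the wall exceeds
#' the far-field density by roughly `cosh(grading)`, which resolves thin
#' boundary layers without wasting nodes where the solution is flat.
#' `grading = 0` gives a uniform mesh.
#'
#' @param eta_inf domain truncation length
#' @param n_nodes number of nodes (>= 5)
#' @param grading sinh grading strength (0 = uniform; default 3)
#' @return strictly increasing numeric vector from 0 to `eta_inf`
#' @export
make_mesh <- function(eta_inf, n_nodes, grading = 3) {
  stopifnot(eta_inf > 0, n_nodes >= 5)
  x <- seq(0, 1, length.out = n_nodes)
  if (grading <= 0) return(eta_inf * x)
  eta_inf * sinh(grading * x) / sinh(grading)
}

# Numeric Jacobian of a vectorized rhs at every node: returns n x n x N.
.jac_nodes <- function(rhs, eta, U, F0) {
  n <- nrow(U); N <- ncol(U)
  J <- array(0, dim = c(n, n, N))
  sq <- sqrt(.Machine$double.eps)
  for (j in seq_len(n)) {
    step <- sq * (abs(U[j, ]) + 1)
    Up <- U
    Up[j, ] <- Up[j, ] + step
    J[, j, ] <- (rhs(eta, Up) - F0) / rep(step, each = n)
  }
  J
}

.colloc_residual <- function(rhs, bc, eta, U, h) {
  n <- nrow(U); N <- ncol(U)
  Fv <- rhs(eta, U)
  hh <- rep(h, each = n)
  Um <- (U[, -N, drop = FALSE] + U[, -1, drop = FALSE]) / 2 +
    (hh / 8) * (Fv[, -N, drop = FALSE] - Fv[, -1, drop = FALSE])
  etam <- (eta[-N] + eta[-1]) / 2
  Fm <- rhs(etam, Um)
  Rint <- U[, -1, drop = FALSE] - U[, -N, drop = FALSE] -
    (hh / 6) * (Fv[, -N, drop = FALSE] + 4 * Fm + Fv[, -1, drop = FALSE])
  list(res = c(Rint, bc(U[, 1], U[, N])), Fv = Fv, Um = Um, etam = etam)
}

.colloc_jacobian <- function(rhs, bc, eta, U, h, parts) {
  n <- nrow(U); N <- ncol(U)
  Jn <- .jac_nodes(rhs, eta, U, parts$Fv)
  Jm <- .jac_nodes(rhs, parts$etam, parts$Um, rhs(parts$etam, parts$Um))
  I <- diag(n)
  Ablk <- array(0, dim = c(n, n, N - 1))
  Bblk <- array(0, dim = c(n, n, N - 1))
  for (i in seq_len(N - 1)) {
    Ji <- Jn[, , i]; Jk <- Jn[, , i + 1]; Jmi <- Jm[, , i]
    hi <- h[i]
    Ablk[, , i] <- -I - (hi / 6) * (Ji + 4 * Jmi %*% (I / 2 + (hi / 8) * Ji))
    Bblk[, , i] <-  I - (hi / 6) * (Jk + 4 * Jmi %*% (I / 2 - (hi / 8) * Jk))
  }
  # boundary-condition Jacobian (numeric)
  sq <- sqrt(.Machine$double.eps)
  ua <- U[, 1]; ub <- U[, N]
  bc0 <- bc(ua, ub)
  Ja <- Jb <- matrix(0, n, n)
  for (j in seq_len(n)) {
    st <- sq * (abs(ua[j]) + 1)
    up <- ua; up[j] <- up[j] + st
    Ja[, j] <- (bc(up, ub) - bc0) / st
    st <- sq * (abs(ub[j]) + 1)
    up <- ub; up[j] <- up[j] + st
    Jb[, j] <- (bc(ua, up) - bc0) / st
  }
  base <- (seq_len(N - 1) - 1) * n
  rA <- rep(rep(seq_len(n), times = n), N - 1) + rep(base, each = n * n)
  cA <- rep(rep(seq_len(n), each = n), N - 1) + rep(base, each = n * n)
  bcrow <- (N - 1) * n + seq_len(n)
  ii <- c(rA, rA, rep(bcrow, times = n), rep(bcrow, times = n))
  jj <- c(cA, cA + n, rep(seq_len(n), each = n),
          (N - 1) * n + rep(seq_len(n), each = n))
  xx <- c(as.vector(Ablk), as.vector(Bblk), as.vector(Ja), as.vector(Jb))
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n * N, n * N))
}

#' Solve a first-order two-point BVP by Lobatto IIIA collocation
#'
#' @param rhs vectorized right-hand side: `rhs(eta, U)` with `U` an
#'   `n x N` state matrix returns the `n x N` matrix of derivatives
#' @param bc boundary function: `bc(u_at_0, u_at_inf)` returns `n` residuals
#' @param eta strictly increasing mesh (see [make_mesh])
#' @param U0 `n x N` initial iterate
#' @param tol Newton tolerance on the max-norm of all residuals
#' @param max_newton iteration cap
#' @param linear set `TRUE` for affine problems (single undamped step)
#' @return list with elements `U` (solution matrix), `res_norm`,
#'   `iterations`, `converged`
#' @export
colloc_solve <- function(rhs, bc, eta, U0, tol = 1e-8, max_newton = 25,
                         linear = FALSE) {
  stopifnot(is.matrix(U0), ncol(U0) == length(eta), all(diff(eta) > 0))
  n <- nrow(U0); N <- length(eta); h <- diff(eta)
  U <- U0
  parts <- .colloc_residual(rhs, bc, eta, U, h)
  rn <- max(abs(parts$res))
  iter <- 0L
  stall <- 0L
  while (rn > tol && iter < max_newton) {
    iter <- iter + 1L
    Jac <- .colloc_jacobian(rhs, bc, eta, U, h, parts)
    dx <- tryCatch(
      as.numeric(Matrix::solve(Jac, -parts$res)),
      error = function(e) stop("collocation Jacobian is singular: ",
                               conditionMessage(e), call. = FALSE))
    dU <- matrix(dx, n, N)
    if (linear) {
      U <- U + dU
      parts <- .colloc_residual(rhs, bc, eta, U, h)
      rn <- max(abs(parts$res))
      next
    }
    accepted <- FALSE
    for (alpha in 2^(0:-8)) {
      Utry <- U + alpha * dU
      ptry <- tryCatch(.colloc_residual(rhs, bc, eta, Utry, h),
                       error = function(e) NULL)
      if (is.null(ptry) || !all(is.finite(ptry$res))) next
      rtry <- max(abs(ptry$res))
      if (rtry < (1 - 1e-4 * alpha) * rn || rtry < tol) {
        U <- Utry; parts <- ptry; rn <- rtry; accepted <- TRUE
        break
      }
    }
    if (!accepted) {
      stall <- stall + 1L
      if (stall >= 3L) break
      # take the least-damped finite step anyway and keep going
      Utry <- U + 2^-8 * dU
      ptry <- tryCatch(.colloc_residual(rhs, bc, eta, Utry, h),
                       error = function(e) NULL)
      if (is.null(ptry) || !all(is.finite(ptry$res))) break
      U <- Utry; parts <- ptry; rn <- max(abs(ptry$res))
    } else {
      stall <- 0L
    }
  }
  list(U = U, res_norm = rn, iterations = iter, converged = rn <= tol)
}
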