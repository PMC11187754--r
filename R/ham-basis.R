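# Exponential-polynomial HAM path (flat configurations).
#
# For a flat-sheet configuration every deformation component of the
# homotopy series stays inside span{ eta^j exp(-n eta) : n >= 0, j >= 0 }
# when the initial guesses are 1 - e^-eta / e^-eta: products, derivatives
# and the auxiliary-operator inverses are all closed in this space.  This
# module implements that algebra numerically — a faithful double-precision
# version of the pen-and-paper HAM recursion — with functions represented
# as coefficient tables C[n+1, j+1] (coefficient of eta^j e^{-n eta}).
# Products are 2-D convolutions (via FFT); L-inverses are exact per-term
# recurrences, including the secular (resonant) n = 1 terms that acquire an
# extra power of eta.
#
# The curved-surface path (rational coefficients 1/(eta+K), not closed in
# any exponential basis) uses the grid-based solver in ham.R instead.

.ep_trim <- function(C, tol = 1e-300) {
  nr <- nrow(C); nc <- ncol(C)
  while (nr > 1 && all(C[nr, ] == 0)) nr <- nr - 1
  while (nc > 1 && all(C[, nc] == 0)) nc <- nc - 1
  C[seq_len(nr), seq_len(nc), drop = FALSE]
}

.ep_const <- function(v = 0) matrix(as.complex(v), 1, 1)

.ep_pad <- function(C, nr, nc) {
  out <- matrix(0i, nr, nc)
  out[seq_len(nrow(C)), seq_len(ncol(C))] <- C
  out
}

.ep_add <- function(A, B) {
  nr <- max(nrow(A), nrow(B)); nc <- max(ncol(A), ncol(B))
  .ep_pad(A, nr, nc) + .ep_pad(B, nr, nc)
}

.ep_mul <- function(A, B) {
  nr <- nrow(A) + nrow(B) - 1L
  nc <- ncol(A) + ncol(B) - 1L
  FA <- stats::fft(.ep_pad(A, nr, nc))
  FB <- stats::fft(.ep_pad(B, nr, nc))
  C <- stats::fft(FA * FB, inverse = TRUE) / (nr * nc)
  mx <- max(Mod(C))
  if (mx > 0) C[Mod(C) < 1e-14 * mx] <- 0i
  .ep_trim(C)
}

# multiply by eta (shift polynomial degree)
.ep_eta <- function(A) cbind(matrix(0i, nrow(A), 1), A)

# d/d eta of sum C[n,j] eta^j e^{-n eta}
.ep_deriv <- function(C) {
  nr <- nrow(C); nc <- ncol(C)
  out <- matrix(0i, nr, nc)
  # -n * term
  out <- out - C * matrix(0:(nr - 1), nr, nc)
  # j * eta^{j-1}
  if (nc > 1) out[, 1:(nc - 1)] <- out[, 1:(nc - 1)] +
    C[, 2:nc, drop = FALSE] * matrix(1:(nc - 1), nr, nc - 1, byrow = TRUE)
  .ep_trim(out)
}

.ep_eval <- function(C, eta, deriv = 0) {
  while (deriv > 0) { C <- .ep_deriv(C); deriv <- deriv - 1 }
  out <- numeric(length(eta))
  for (n in seq_len(nrow(C)) - 1L) {
    co <- C[n + 1L, ]
    if (all(co == 0)) next
    pv <- rep(0+0i, length(eta))
    for (j in rev(seq_along(co)) - 1L) pv <- pv * eta + co[j + 1L]
    out <- out + Re(pv * exp(-n * eta))
  }
  out
}

.ep_max_resid <- function(C, eta) max(abs(.ep_eval(C, eta)))

# Solve w'' - w = poly(eta) * e^{-n eta} for one n-row; returns the
# polynomial coefficient vector of w (same exponential rate), whose degree
# rises by one in the resonant case n = 1 (n = -1 cannot arise: n >= 0).
.psolve2 <- function(n, co) {
  J <- length(co) - 1L
  a2 <- as.complex(n^2 - 1)
  if (n != 1) {
    w <- rep(0i, J + 1L)
    for (j in J:0) {
      v <- co[j + 1L]
      if (j + 1L <= J) v <- v + 2 * n * (j + 1) * w[j + 2L]
      if (j + 2L <= J) v <- v - (j + 2) * (j + 1) * w[j + 3L]
      w[j + 1L] <- v / a2
    }
    w
  } else {
    # resonance: w = e^{-eta} * q(eta) with q of degree J+1, q(0) free (0)
    w <- rep(0i, J + 2L)   # q coefficients, q_0 stays 0
    for (j in (J + 1L):1L) {
      v <- co[j]           # rhs coefficient of eta^{j-1}
      if (j + 1L <= J + 1L) v <- v - (j + 1) * j * w[j + 2L]
      w[j + 1L] <- -v / (2 * j)
    }
    w
  }
}

# integrate poly(eta)*e^{-n eta} (n >= 1): by parts; returns list(poly, const)
.pint_exp <- function(n, co) {
  J <- length(co) - 1L
  out <- rep(0i, J + 1L)
  # I_j = int eta^j e^{-n eta} = -eta^j e^{-n eta}/n + (j/n) I_{j-1}
  for (j in J:0) {
    out[j + 1L] <- out[j + 1L] - co[j + 1L] / n
    if (j >= 1) co[j] <- co[j] + co[j + 1L] * j / n
  }
  list(poly = out, const = -out[1L] * 0)  # definite constant fixed later
}

# Solve L u = r for the second-order operators (u'' - u), BC u(0) = target,
# decaying kernel e^{-eta}; constants (n = 0 rows) get particular -poly''..
.ep_solve2 <- function(r, target = 0) {
  u <- .ep_const(0)
  for (n in seq_len(nrow(r)) - 1L) {
    co <- r[n + 1L, ]
    if (all(co == 0)) next
    if (n == 0) {
      # (d^2 - 1) w = poly: w = -(poly + poly'' + poly'''' + ...)
      w <- rep(0i, length(co))
      cur <- co
      repeat {
        w <- w + cur
        J <- length(cur) - 1L
        if (J < 2) break
        nxt <- rep(0i, max(1L, J - 1L))
        for (j in 2:J) nxt[j - 1L] <- nxt[j - 1L] + j * (j - 1) * cur[j + 1L]
        cur <- nxt
        if (all(cur == 0)) break
      }
      term <- matrix(-w, 1)
    } else {
      w <- .psolve2(n, co)
      term <- matrix(0i, n + 1L, length(w))
      term[n + 1L, ] <- w
    }
    u <- .ep_add(u, term)
  }
  # kernel e^{-eta}: u(0) = target
  u0 <- sum(vapply(seq_len(nrow(u)), function(i) u[i, 1L], complex(1)))
  ker <- matrix(0i, 2, 1); ker[2, 1] <- as.complex(target) - u0
  .ep_trim(.ep_add(u, ker))
}

# Solve u''' - u' = r with u(0) = 0, u'(0) = 0 (kernel {1, e^{-eta}};
# e^{+eta} excluded by decay).  Via v = u': v'' - v = r, then integrate.
.ep_solve_f <- function(r) {
  v <- .ep_solve2(r, target = 0)  # v(0) = 0 picks a valid kernel choice
  # integrate v row by row
  u <- .ep_const(0)
  for (n in seq_len(nrow(v)) - 1L) {
    co <- v[n + 1L, ]
    if (all(co == 0)) next
    if (n == 0) {
      J <- length(co) - 1L
      poly <- rep(0i, J + 2L)
      for (j in 0:J) poly[j + 2L] <- co[j + 1L] / (j + 1)
      term <- matrix(poly, 1)
    } else {
      ip <- .pint_exp(n, co)
      term <- matrix(0i, n + 1L, length(ip$poly))
      term[n + 1L, ] <- ip$poly
    }
    u <- .ep_add(u, term)
  }
  # constants: u(0) = 0 (u'(0) = v(0) = 0 already)
  u0 <- sum(vapply(seq_len(nrow(u)), function(i) u[i, 1L], complex(1)))
  .ep_trim(.ep_add(u, .ep_const(-u0)))
}

# Residual operators for the FLAT configuration on tables.  fields is a
# list with tables f, g, th, ch; derivatives are taken symbolically.
.ep_flat_residuals <- function(fields, params, ratios) {
  p <- params; r <- ratios
  f <- fields$f; g <- fields$g; th <- fields$th; ch <- fields$ch
  fp <- .ep_deriv(f); fpp <- .ep_deriv(fp); fppp <- .ep_deriv(fpp)
  fiv <- .ep_deriv(fppp)
  gp <- .ep_deriv(g); gpp <- .ep_deriv(gp)
  thp <- .ep_deriv(th); thpp <- .ep_deriv(thp)
  chp <- .ep_deriv(ch); chpp <- .ep_deriv(chp)
  visc <- r$mu_r + p$K1 + p$alpha1
  sink <- r$sigma_r * p$M + r$mu_r * p$beta0

  mom <- .ep_add(.ep_add(visc * fiv, -sink * fpp), -p$K1 * gpp)
  if (p$alpha2 != 0) {
    cub <- .ep_add(.ep_mul(.ep_mul(fpp, fpp), fiv),
                   2 * .ep_mul(fpp, .ep_mul(fppp, fppp)))
    mom <- .ep_add(mom, -p$alpha2 * cub)
  }
  mom <- .ep_add(mom, r$rho_r * .ep_add(.ep_mul(f, fppp),
                                        -1 * .ep_mul(fp, fpp)))
  if (p$gamma != 0) {
    mom <- .ep_add(mom, -p$gamma * .ep_add(0.5 * .ep_eta(fppp), 1.5 * fpp))
  }

  micro <- .ep_add((r$mu_r + p$K1 / 2) * gpp,
                   .ep_add(.ep_mul(f, gp), -1 * .ep_mul(fp, g)))
  micro <- .ep_add(micro, -p$K1 * .ep_add(2 * g, fpp))
  if (p$gamma != 0) {
    micro <- .ep_add(micro, -(p$gamma / 2) * .ep_add(.ep_eta(gp), 3 * g))
  }

  energy <- r$k_r * thpp
  if (p$beta != 0) {
    energy <- .ep_add(energy, r$k_r * p$beta *
                        .ep_add(.ep_mul(th, thpp), .ep_mul(thp, thp)))
  }
  if (p$M != 0 && p$Ec != 0) {
    energy <- .ep_add(energy, r$sigma_r * p$M * p$Pr * p$Ec * .ep_mul(fp, fp))
  }
  conv <- .ep_mul(f, thp)
  if (p$gamma != 0) conv <- .ep_add(conv, -(p$gamma / 2) * .ep_eta(thp))
  energy <- .ep_add(energy, r$rhocp_r * p$Pr * conv)
  if (p$Q != 0) energy <- .ep_add(energy, p$Pr * p$Q * th)

  bact <- chpp
  convb <- .ep_mul(f, chp)
  if (p$gamma != 0) convb <- .ep_add(convb, -(p$gamma / 2) * .ep_eta(chp))
  bact <- .ep_add(bact, p$Lb * convb)
  if (p$lam != 0) {
    bact <- .ep_add(bact, p$lam * .ep_add(.ep_const(p$Omega), ch))
  }
  list(mom = mom, micro = micro, energy = energy, bact = bact)
}

# Run the exponential-basis HAM recursion for a flat configuration.
.ham_run_basis <- function(params, ratios, hbar, order, eta,
                           on_divergence = c("error", "continue")) {
  on_divergence <- match.arg(on_divergence)
  e1 <- matrix(c(0i, 1 + 0i), 2, 1)          # e^{-eta}
  one <- .ep_const(1)
  u0 <- list(f = .ep_add(one, -1 * e1), g = params$m0 * e1,
             th = e1, ch = e1)
  orders <- list(u0)
  racc <- list(f = .ep_const(0), g = .ep_const(0),
               th = .ep_const(0), ch = .ep_const(0))
  hist <- matrix(NA_real_, order, 4,
                 dimnames = list(NULL, c("momentum", "microrotation",
                                         "energy", "bacteria")))
  grow <- 0L
  diverged_at <- NA_integer_
  for (m in seq_len(order)) {
    D <- 3L * (m - 1L) + 1L
    acc <- list(mom = .ep_const(0), micro = .ep_const(0),
                energy = .ep_const(0), bact = .ep_const(0))
    for (j in seq_len(D) - 1L) {
      q <- exp(2i * pi * j / D)
      qs <- q^(seq_len(m) - 1L)
      comb <- lapply(c(f = "f", g = "g", th = "th", ch = "ch"), function(fd) {
        out <- orders[[1]][[fd]]
        if (m >= 2) for (k in 2:m) out <- .ep_add(out, qs[k] * orders[[k]][[fd]])
        out
      })
      eq <- .ep_flat_residuals(comb, params, ratios)
      w <- exp(-2i * pi * j * (m - 1L) / D) / D
      acc$mom <- .ep_add(acc$mom, w * eq$mom)
      acc$micro <- .ep_add(acc$micro, w * eq$micro)
      acc$energy <- .ep_add(acc$energy, w * eq$energy)
      acc$bact <- .ep_add(acc$bact, w * eq$bact)
    }
    Rm <- lapply(acc, function(C) .ep_trim(matrix(complex(real = Re(C)),
                                                  nrow(C), ncol(C))))
    racc$f <- .ep_add(racc$f, hbar[["f"]] * Rm$mom)
    racc$g <- .ep_add(racc$g, hbar[["g"]] * Rm$micro)
    racc$th <- .ep_add(racc$th, hbar[["theta"]] * Rm$energy)
    racc$ch <- .ep_add(racc$ch, hbar[["chi"]] * Rm$bact)

    fm <- .ep_solve_f(racc$f)
    fpp0 <- Re(.ep_eval(fm, 0, deriv = 2))
    gm <- .ep_solve2(racc$g, target = -params$m0 * fpp0)
    tm <- .ep_solve2(racc$th, target = 0)
    cm <- .ep_solve2(racc$ch, target = 0)
    orders[[m + 1L]] <- list(f = fm, g = gm, th = tm, ch = cm)

    part <- lapply(c(f = "f", g = "g", th = "th", ch = "ch"), function(fd) {
      Reduce(.ep_add, lapply(orders, `[[`, fd))
    })
    eq <- .ep_flat_residuals(part, params, ratios)
    hist[m, ] <- c(.ep_max_resid(eq$mom, eta), .ep_max_resid(eq$micro, eta),
                   .ep_max_resid(eq$energy, eta), .ep_max_resid(eq$bact, eta))
    if (m >= 2 && max(hist[m, ]) > 1.2 * max(hist[m - 1, ])) grow <- grow + 1L
    else grow <- 0L
    if (grow >= 3L && is.na(diverged_at)) {
      diverged_at <- m
      if (on_divergence == "error") {
        stop(sprintf(
          "HAM residual grew for 3 consecutive orders (order %d); re-select hbar via hbar_curve()", m))
      }
    }
  }
  # export on the grid in the shape the grid path uses
  to_grid <- function(o) {
    list(f = do.call(rbind, stats::setNames(lapply(0:4, function(d)
           .ep_eval(o$f, eta, d)), paste0("d", 0:4))),
         g = do.call(rbind, stats::setNames(lapply(0:2, function(d)
           .ep_eval(o$g, eta, d)), paste0("d", 0:2))),
         theta = do.call(rbind, stats::setNames(lapply(0:2, function(d)
           .ep_eval(o$th, eta, d)), paste0("d", 0:2))),
         chi = do.call(rbind, stats::setNames(lapply(0:2, function(d)
           .ep_eval(o$ch, eta, d)), paste0("d", 0:2))))
  }
  comps <- lapply(orders[seq_len(order + 1L)], to_grid)
  partial <- Reduce(function(a, b) Map(`+`, a, b), comps)
  structure(list(eta = eta, components = comps, partial_sum = partial,
                 order_used = order, residual_history = hist,
                 diverged_at = diverged_at,
                 hbar = hbar, params = params, ratios = ratios,
                 basis = "exponential"),
            class = "hnf_ham")
}
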