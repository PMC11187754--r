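# Numerical homotopy analysis method (HAM).
#
# The nonlinear system N[u] = 0 (the four similarity equations) is embedded
# in the homotopy (1-q) L[Phi - u0] = q hbar N[Phi]; expanding Phi in powers
# of the embedding parameter q gives order equations
#
#   L[u_m - chi_m u_{m-1}] = hbar R_m,   chi_1 = 0, chi_m = 1 (m >= 2),
#
# with R_m the q^(m-1) Taylor coefficient of N[sum u_k q^k].  Deformation
# components are represented on an eta-grid and each order is solved as a
# linear two-point BVP with the auxiliary operators
#
#   L_f = f''' - f',   L_g = g'' - g,   L_th = th'' - th,   L_ch = ch'' - ch
#
# whose kernels (c1 + c2 e^-eta + c3 e^eta, c e^-eta + c e^eta, ...) supply
# exponentially decaying homogeneous solutions.  (The third-order L_f is the
# operator the printed kernel property pins down; a second-order operator
# cannot carry the three boundary constraints each f-order needs.)
#
# R_m is extracted *exactly* (to round-off) by evaluating N on the partial
# series at complex roots of unity and taking a discrete Fourier transform:
# N is polynomial in q of degree <= 3(m-1) (the sharpest nonlinearity is the
# Eyring-Powell cubic), so 3(m-1)+1 evaluation points suffice.

#' HAM solver configuration
#'
#' @param order truncation order of the homotopy series (>= 1)
#' @param hbar_f,hbar_g,hbar_theta,hbar_chi convergence-control parameters
#'   (nonzero; default -1, the homotopy-perturbation choice)
#' @param eta_inf domain length (uniform grid)
#' @param n_nodes number of grid nodes
#' @return object of class `ham_config`
#' @export
ham_config <- function(order = 15, hbar_f = -1, hbar_g = -1,
                       hbar_theta = -1, hbar_chi = -1,
                       eta_inf = 15, n_nodes = 301) {
  stopifnot(order >= 1, n_nodes >= 50, eta_inf > 0)
  hb <- c(f = hbar_f, g = hbar_g, theta = hbar_theta, chi = hbar_chi)
  if (any(hb == 0)) stop("hbar values must be nonzero")
  structure(list(order = as.integer(order), hbar = hb,
                 eta_inf = eta_inf, n_nodes = n_nodes),
            class = "ham_config")
}

.dgrid <- function(eta, y, deriv = 1) {
  stats::splinefun(eta, y, method = "fmm")(eta, deriv = deriv)
}

#' Zeroth-order HAM fields
#'
#' `f0 = 1 - exp(-eta)`, `theta0 = chi0 = exp(-eta)`, and
#' `g0 = -m0 f0''(0) exp(-eta) = m0 exp(-eta)` — the exponential guess
#' rescaled so the configured microrotation wall condition
#' `g(0) = -m0 f''(0)` holds at order zero (it vanishes identically at the
#' default `m0 = 0`, matching the strong-concentration wall condition).
#'
#' @param grid eta grid (increasing, starting at 0)
#' @param params a [flow_params]
#' @return list with matrices `f` (rows `d0..d4`: value and derivatives),
#'   `g`, `theta`, `chi` (rows `d0..d2`)
#' @export
ham_initial_guess <- function(grid, params) {
  e <- exp(-grid)
  f <- rbind(d0 = 1 - e, d1 = e, d2 = -e, d3 = e, d4 = -e)
  list(f = f,
       g = params$m0 * rbind(d0 = e, d1 = -e, d2 = e),
       theta = rbind(d0 = e, d1 = -e, d2 = e),
       chi = rbind(d0 = e, d1 = -e, d2 = e))
}

#' Apply an auxiliary linear HAM operator to a grid function
#'
#' `which = "f"` applies `f''' - f'` (the operator whose kernel is
#' `c1 + c2 exp(-eta) + c3 exp(eta)`); `"g"`, `"theta"`, `"chi"` apply
#' `u'' - u`.  Derivatives are taken with cubic-spline differentiation, so
#' accuracy is limited by the grid spacing (O(h) for the third derivative);
#' this operator is a diagnostic, not part of the solve path.
#'
#' @param field_values numeric vector of field values on `grid`
#' @param which one of `"f"`, `"g"`, `"theta"`, `"chi"`
#' @param grid the eta grid
#' @return numeric vector of operator values
#' @export
apply_linear_operator <- function(field_values, which = c("f", "g", "theta", "chi"),
                                  grid) {
  which <- match.arg(which)
  if (which == "f") {
    # third derivative via two spline passes (second derivative, then one
    # more differentiation) — O(h^2) instead of the O(h) piecewise-constant
    # third derivative of a single cubic spline
    d3 <- .dgrid(grid, .dgrid(grid, field_values, 2), 1)
    d3 - .dgrid(grid, field_values, 1)
  } else {
    .dgrid(grid, field_values, 2) - field_values
  }
}

# ---- internal context: grid + prefactored linear operators -----------------

.ham_field_def <- function(which) {
  if (which == "f") {
    list(nc = 3L,
         rhs = function(rfun) function(e, Y)
           rbind(Y[2, , drop = FALSE], Y[3, , drop = FALSE],
                 Y[2, , drop = FALSE] + rep(rfun(e), each = 1)),
         bc = function(target) function(ua, ub) c(ua[1], ua[2], ub[2]))
  } else {
    list(nc = 2L,
         rhs = function(rfun) function(e, Y)
           rbind(Y[2, , drop = FALSE], Y[1, , drop = FALSE] + rfun(e)),
         bc = function(target) function(ua, ub) c(ua[1] - target, ub[1]))
  }
}

.ham_context <- function(params, ratios, config) {
  eta <- seq(0, config$eta_inf, length.out = config$n_nodes)
  h <- diff(eta)
  zero_r <- function(e) rep(0, length(e))
  ops <- list()
  for (which in c("f", "g", "theta", "chi")) {
    def <- .ham_field_def(which)
    rhs0 <- def$rhs(zero_r)
    bc0 <- def$bc(0)
    U0 <- matrix(0, def$nc, length(eta))
    parts <- .colloc_residual(rhs0, bc0, eta, U0, h)
    J <- .colloc_jacobian(rhs0, bc0, eta, U0, h, parts)
    ops[[which]] <- list(def = def, lu = Matrix::lu(J))
  }
  list(eta = eta, h = h, params = params, ratios = ratios, ops = ops)
}

# Solve L u = r with the prefactored operator; returns nc x N state matrix.
.ham_linear_solve <- function(ctx, which, r, target = 0) {
  op <- ctx$ops[[which]]
  rfun <- stats::splinefun(ctx$eta, r, method = "fmm")
  rhs <- op$def$rhs(rfun)
  bcf <- op$def$bc(target)
  U0 <- matrix(0, op$def$nc, length(ctx$eta))
  parts <- .colloc_residual(rhs, bcf, ctx$eta, U0, ctx$h)
  x <- as.numeric(Matrix::solve(op$lu, -parts$res))
  matrix(x, op$def$nc, length(ctx$eta))
}

# Evaluate the four equation residuals for a (possibly complex) combined
# state given as the ham field lists.
.ham_residuals <- function(ctx, f, g, th, ch) {
  U <- rbind(f = f["d0", ], fp = f["d1", ], fpp = f["d2", ], fppp = f["d3", ],
             g = g["d0", ], gp = g["d1", ],
             theta = th["d0", ], thetap = th["d1", ],
             chi = ch["d0", ], chip = ch["d1", ])
  rownames(U) <- .state_names
  .eq_residuals(ctx$eta, U, f["d4", ], g["d2", ], th["d2", ], ch["d2", ],
                ctx$params, ctx$ratios)
}

# Exact extraction of R_m = [q^(m-1)] N[sum_k u_k q^k] by DFT over roots of
# unity (N is polynomial in q of degree <= 3(m-1)).
.ham_extract <- function(ctx, orders, m) {
  D <- 3L * (m - 1L) + 1L
  N <- length(ctx$eta)
  acc <- list(mom = 0+0i, micro = 0+0i, energy = 0+0i, bact = 0+0i)
  for (j in seq_len(D) - 1L) {
    q <- exp(2i * pi * j / D)
    qs <- q^(seq_len(m) - 1L)          # q^0 .. q^(m-1)
    comb <- function(field) {
      out <- orders[[1]][[field]] * (1+0i)
      if (m >= 2) for (k in 2:m) out <- out + orders[[k]][[field]] * qs[k]
      out
    }
    eq <- .ham_residuals(ctx, comb("f"), comb("g"), comb("theta"), comb("chi"))
    w <- exp(-2i * pi * j * (m - 1L) / D)
    acc$mom <- acc$mom + eq$mom * w
    acc$micro <- acc$micro + eq$micro * w
    acc$energy <- acc$energy + eq$energy * w
    acc$bact <- acc$bact + eq$bact * w
  }
  lapply(acc, function(v) Re(v) / D)
}

.ham_run <- function(ctx, hbar, order, seed_state = NULL,
                     on_divergence = c("error", "continue")) {
  on_divergence <- match.arg(on_divergence)
  eta <- ctx$eta
  u0 <- if (is.null(seed_state)) ham_initial_guess(eta, ctx$params) else seed_state
  orders <- list(u0)
  partial <- u0
  racc <- list(f = 0 * eta, g = 0 * eta, theta = 0 * eta, chi = 0 * eta)
  hist <- matrix(NA_real_, order, 4,
                 dimnames = list(NULL, c("momentum", "microrotation",
                                         "energy", "bacteria")))
  grow <- 0L
  diverged_at <- NA_integer_
  for (m in seq_len(order)) {
    Rm <- .ham_extract(ctx, orders, m)
    racc$f <- racc$f + hbar[["f"]] * Rm$mom
    racc$g <- racc$g + hbar[["g"]] * Rm$micro
    racc$theta <- racc$theta + hbar[["theta"]] * Rm$energy
    racc$chi <- racc$chi + hbar[["chi"]] * Rm$bact

    yf <- .ham_linear_solve(ctx, "f", racc$f)
    f3 <- yf[2, ] + racc$f                       # u''' = u' + r
    f4 <- yf[3, ] + .dgrid(eta, racc$f)          # u'''' = u'' + r'
    fm <- rbind(d0 = yf[1, ], d1 = yf[2, ], d2 = yf[3, ], d3 = f3, d4 = f4)

    g_target <- -ctx$params$m0 * fm["d2", 1]
    yg <- .ham_linear_solve(ctx, "g", racc$g, target = g_target)
    gm <- rbind(d0 = yg[1, ], d1 = yg[2, ], d2 = yg[1, ] + racc$g)
    yt <- .ham_linear_solve(ctx, "theta", racc$theta)
    tm <- rbind(d0 = yt[1, ], d1 = yt[2, ], d2 = yt[1, ] + racc$theta)
    yc <- .ham_linear_solve(ctx, "chi", racc$chi)
    cm <- rbind(d0 = yc[1, ], d1 = yc[2, ], d2 = yc[1, ] + racc$chi)

    comp <- list(f = fm, g = gm, theta = tm, chi = cm)
    orders[[m + 1L]] <- comp
    partial <- Map(`+`, partial, comp)

    eq <- .ham_residuals(ctx, partial$f, partial$g, partial$theta, partial$chi)
    hist[m, ] <- c(max(abs(eq$mom)), max(abs(eq$micro)),
                   max(abs(eq$energy)), max(abs(eq$bact)))
    if (m >= 2 && max(hist[m, ]) > 1.2 * max(hist[m - 1, ])) {
      grow <- grow + 1L
    } else {
      grow <- 0L
    }
    if (grow >= 3L && is.na(diverged_at)) {
      diverged_at <- m
      if (on_divergence == "error") {
        stop(sprintf(
          "HAM residual grew for 3 consecutive orders (order %d); re-select hbar via hbar_curve()", m))
      }
    }
  }
  structure(list(eta = eta, components = orders, partial_sum = partial,
                 order_used = order, residual_history = hist,
                 diverged_at = diverged_at,
                 hbar = hbar, params = ctx$params, ratios = ctx$ratios),
            class = "hnf_ham")
}

#' Solve the coupled system by the homotopy analysis method
#'
#' Runs the order-by-order deformation equations up to `config$order`,
#' recording the maximum equation residual of the partial sum at every
#' order.  Deterministic for a fixed configuration.  If the residual grows
#' for three consecutive orders the run stops with an error suggesting
#' h-bar re-selection (set `on_divergence = "continue"` to keep the partial
#' sums, e.g. when scanning an h-bar curve).
#'
#' @param params a [flow_params]
#' @param ratios a [mixture_ratios]
#' @param config a [ham_config]
#' @param seed_state optional zeroth-order override (same shape as
#'   [ham_initial_guess]); used by the fixed-point diagnostics
#' @param on_divergence `"error"` (default) or `"continue"`
#' @return object of class `hnf_ham` with per-order `components`,
#'   `partial_sum`, `order_used` and `residual_history`
#' @export
ham_solve <- function(params, ratios = unit_ratios(), config = ham_config(),
                      seed_state = NULL, on_divergence = "error") {
  if (is.infinite(params$K) && is.null(seed_state)) {
    # flat configurations: exact exponential-polynomial recursion (the
    # pen-and-paper HAM algebra, see ham-basis.R)
    eta <- seq(0, config$eta_inf, length.out = config$n_nodes)
    return(.ham_run_basis(params, ratios, config$hbar, config$order, eta,
                          on_divergence = on_divergence))
  }
  ctx <- .ham_context(params, ratios, config)
  .ham_run(ctx, config$hbar, config$order, seed_state = seed_state,
           on_divergence = on_divergence)
}

#' @export
print.hnf_ham <- function(x, ...) {
  cat(sprintf("<hnf_ham> order %d on %d nodes, hbar = (%s)\n",
              x$order_used, length(x$eta),
              paste(sprintf("%g", x$hbar), collapse = ", ")))
  cat(sprintf("  final max residuals: %s\n",
              paste(sprintf("%.2e", x$residual_history[x$order_used, ]),
                    collapse = " ")))
  invisible(x)
}

#' Compute one HAM deformation order
#'
#' Returns a new `hnf_ham` object extended by one order (index
#' `solution$order_used + 1`).  Exposed for step-by-step inspection; the
#' batch driver is [ham_solve].
#'
#' @param solution an `hnf_ham` object
#' @param params,ratios,config as in [ham_solve] (the grid must match)
#' @return an `hnf_ham` with one more order
#' @export
ham_deformation_step <- function(solution, params = solution$params,
                                 ratios = solution$ratios,
                                 config = ham_config(
                                   order = solution$order_used + 1L,
                                   eta_inf = max(solution$eta),
                                   n_nodes = length(solution$eta))) {
  config$hbar <- solution$hbar
  seed <- if (is.null(solution$basis)) solution$components[[1]] else NULL
  ham_solve(params, ratios, config, seed_state = seed,
            on_divergence = "continue")
}

#' h-bar convergence-control curve
#'
#' Evaluates a wall quantity of the fixed-order partial sum across a range
#' of the convergence-control parameter (the same h-bar is applied to all
#' four fields).  The flat plateau of the curve identifies admissible
#' values.
#'
#' @param params a [flow_params]
#' @param ratios a [mixture_ratios]
#' @param quantity one of `"fpp0"` (`f''(0)`), `"thetap0"`, `"gp0"`,
#'   `"chip0"`
#' @param hbar_range numeric vector of h-bar values (must exclude 0)
#' @param order fixed truncation order (default 10)
#' @param config a [ham_config] supplying grid settings
#' @return data.frame with columns `hbar` and `value`
#' @export
hbar_curve <- function(params, ratios = unit_ratios(),
                       quantity = c("fpp0", "thetap0", "gp0", "chip0"),
                       hbar_range = seq(-1.8, -0.2, by = 0.1),
                       order = 10, config = ham_config(order = order)) {
  quantity <- match.arg(quantity)
  if (any(hbar_range == 0)) stop("hbar_range must exclude 0")
  flat <- is.infinite(params$K)
  if (!flat) ctx <- .ham_context(params, ratios, config)
  eta <- seq(0, config$eta_inf, length.out = config$n_nodes)
  pick <- function(run) switch(quantity,
    fpp0 = run$partial_sum$f["d2", 1],
    thetap0 = run$partial_sum$theta["d1", 1],
    gp0 = run$partial_sum$g["d1", 1],
    chip0 = run$partial_sum$chi["d1", 1])
  vals <- vapply(hbar_range, function(hb) {
    hbv <- c(f = hb, g = hb, theta = hb, chi = hb)
    run <- if (flat) {
      .ham_run_basis(params, ratios, hbv, order, eta,
                     on_divergence = "continue")
    } else {
      .ham_run(ctx, hbv, order, on_divergence = "continue")
    }
    pick(run)
  }, numeric(1))
  data.frame(hbar = hbar_range, value = vals)
}

#' Pick a plateau h-bar from an h-bar curve
#'
#' Chooses the grid value where the curve is locally flattest (smallest
#' central-difference slope magnitude), i.e. the middle of the plateau.
#'
#' @param curve a data.frame from [hbar_curve]
#' @return the selected h-bar value
#' @export
hbar_plateau <- function(curve) {
  stopifnot(nrow(curve) >= 3)
  v <- curve$value; hb <- curve$hbar
  slope <- abs((v[-c(1, 2)] - v[-c(nrow(curve) - 1, nrow(curve))]) /
                 (hb[-c(1, 2)] - hb[-c(nrow(curve) - 1, nrow(curve))]))
  hb[which.min(slope) + 1L]
}

#' Compare a HAM solution against a collocation reference
#'
#' Interpolates the collocation profile onto the HAM grid and tabulates,
#' for each of `f'`, `g`, `theta`, `chi`, the HAM value, the reference value
#' and the absolute error (the layout of the standard validation tables).
#'
#' @param ham an `hnf_ham`
#' @param reference an `hnf_profile` from [solve_flow]
#' @param eta_max restrict the comparison to `eta <= eta_max`
#' @return list with `tables` (one data.frame per field) and `summary`
#'   (max and mean absolute error per field)
#' @export
compare_with_collocation <- function(ham, reference, eta_max = Inf) {
  eta <- ham$eta[ham$eta <= eta_max]
  idx <- seq_along(eta)
  ref <- function(row) {
    stats::splinefun(reference$eta, reference$states[row, ],
                     method = "fmm")(eta)
  }
  fields <- list(fp = list(h = ham$partial_sum$f["d1", idx], r = ref("fp")),
                 g = list(h = ham$partial_sum$g["d0", idx], r = ref("g")),
                 theta = list(h = ham$partial_sum$theta["d0", idx],
                              r = ref("theta")),
                 chi = list(h = ham$partial_sum$chi["d0", idx], r = ref("chi")))
  tables <- lapply(fields, function(fl) {
    data.frame(eta = eta, ham = fl$h, reference = fl$r,
               abs_error = abs(fl$h - fl$r))
  })
  summary <- data.frame(
    field = names(tables),
    max_abs_error = vapply(tables, function(t) max(t$abs_error), numeric(1)),
    mean_abs_error = vapply(tables, function(t) mean(t$abs_error), numeric(1)),
    row.names = NULL)
  list(tables = tables, summary = summary)
}
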