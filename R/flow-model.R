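# The dimensionless similarity system.
#
# State ordering (fixed package-wide): f, f', f'', f''', g, g', theta,
# theta', chi, chi'.  The curved-surface geometry enters through
# 1/(eta + K) and K/(eta + K); the exact flat-sheet limit (K = Inf) is a
# sentinel that sets 1/(eta+K) = 0 and K/(eta+K) = 1 analytically, never a
# large finite K (avoids catastrophic cancellation in the eta+K powers).

.state_names <- c("f", "fp", "fpp", "fppp", "g", "gp",
                  "theta", "thetap", "chi", "chip")

.curv <- function(eta, K) {
  if (is.infinite(K)) {
    z <- rep(0, length(eta))
    list(inv = z, kr = z + 1)
  } else {
    list(inv = 1 / (eta + K), kr = K / (eta + K))
  }
}

.as_state <- function(state) {
  if (is.matrix(state)) {
    if (nrow(state) != 10) stop("state matrix must have 10 rows")
    U <- state
  } else {
    if (length(state) != 10) stop("state vector must have 10 components")
    U <- matrix(state, nrow = 10)
  }
  rownames(U) <- .state_names
  U
}

# Residuals of the four transport equations, linear in the highest
# derivatives (fiv, gpp, thetapp, chipp) which are supplied explicitly.
# All arithmetic is complex-safe (used by the HAM order extraction).
# Returns list(mom, micro, energy, bact, coef = list(...)) of vectors.
.eq_residuals <- function(eta, U, fiv, gpp, thetapp, chipp, params, ratios) {
  p <- params; r <- ratios
  cv <- .curv(eta, p$K); iv <- cv$inv; kr <- cv$kr
  f <- U["f", ]; fp <- U["fp", ]; fpp <- U["fpp", ]; fppp <- U["fppp", ]
  g <- U["g", ]; gp <- U["gp", ]
  th <- U["theta", ]; thp <- U["thetap", ]
  ch <- U["chi", ]; chp <- U["chip", ]

  S1 <- fpp + fp * iv                      # shear group
  visc_coef <- r$mu_r + p$K1 + p$alpha1

  mom <- visc_coef * (fiv + 2 * fppp * iv - fpp * iv^2 + fp * iv^3) -
    (r$sigma_r * p$M + r$mu_r * p$beta0) * S1 -
    p$alpha2 * (S1^2 * fiv +
                  (fpp^2 - 3 * fp * fpp * iv - fp^2 * iv^2) * fpp * iv^2 +
                  3 * fp^3 * iv^5 +
                  2 * S1 * fppp^2 +
                  2 * (3 * fpp^2 + 2 * fp * fpp * iv - fp^2 * iv^2) * fppp * iv) -
    p$K1 * (gpp + gp * iv) +
    r$rho_r * (kr * (f * fppp - fp * fpp) +
                 kr * iv * (f * fpp - fp^2) -
                 kr * iv^2 * f * fp) -
    p$gamma * ((eta / 2) * fppp + 1.5 * fpp + ((eta / 2) * fpp + fp) * iv)

  micro <- (r$mu_r + p$K1 / 2) * (gpp + gp * iv) +
    kr * (f * gp - fp * g) -
    p$K1 * (2 * g + fpp + fp * iv) -
    (p$gamma / 2) * (eta * gp + 3 * g)

  energy <- r$k_r * ((1 + p$beta * th) * (thetapp + thp * iv) + p$beta * thp^2) +
    r$sigma_r * p$M * p$Pr * p$Ec * fp^2 +
    r$rhocp_r * p$Pr * (kr * f - p$gamma * eta / 2) * thp +
    p$Pr * p$Q * th

  bact <- chipp + chp * iv +
    p$Lb * (kr * f - p$gamma * eta / 2) * chp +
    p$lam * (p$Omega + ch)

  list(mom = mom, micro = micro, energy = energy, bact = bact,
       coef = list(mom = visc_coef - p$alpha2 * S1^2,
                   micro = r$mu_r + p$K1 / 2,
                   energy = r$k_r * (1 + p$beta * th),
                   bact = rep(1, length(eta))))
}

#' Momentum equation solved for the fourth derivative
#'
#' Returns `f''''` from the curved-surface momentum equation, with every
#' other term (viscous-curvature corrections, Lorentz/porosity sink on the
#' shear group `f'' + f'/(eta+K)`, Eyring-Powell cubic terms, micropolar
#' coupling, convection and unsteadiness) moved to the right-hand side.
#'
#' @param eta similarity coordinate(s)
#' @param state a 10-component state vector in the order
#'   `f, f', f'', f''', g, g', theta, theta', chi, chi'`, or a 10-row matrix
#'   (one column per `eta`)
#' @param params a [flow_params] object
#' @param ratios a [mixture_ratios] object
#' @return value(s) of `f''''`
#' @export
momentum_rhs <- function(eta, state, params, ratios = unit_ratios()) {
  U <- .as_state(state)
  z <- rep(0, length(eta))
  eq <- .eq_residuals(eta, U, z, z, z, z, params, ratios)
  if (any(abs(eq$coef$mom) < 1e-10)) {
    stop("vanishing f'''' coefficient: alpha2 too large for this shear ",
         "(loss of well-posedness; continue from smaller alpha2)")
  }
  # the micropolar coupling needs g'', which the microrotation equation
  # determines from the same state
  gpp <- -eq$micro / eq$coef$micro
  unname(-(eq$mom - params$K1 * gpp) / eq$coef$mom)
}

#' Microrotation equation solved for `g''`
#' @inheritParams momentum_rhs
#' @return value(s) of `g''`
#' @export
microrotation_rhs <- function(eta, state, params, ratios = unit_ratios()) {
  U <- .as_state(state)
  z <- rep(0, length(eta))
  eq <- .eq_residuals(eta, U, z, z, z, z, params, ratios)
  if (any(abs(eq$coef$micro) < 1e-12)) stop("mu_r + K1/2 must be positive")
  unname(-eq$micro / eq$coef$micro)
}

#' Energy equation solved for `theta''`
#' @inheritParams momentum_rhs
#' @return value(s) of `theta''`
#' @export
energy_rhs <- function(eta, state, params, ratios = unit_ratios()) {
  U <- .as_state(state)
  z <- rep(0, length(eta))
  eq <- .eq_residuals(eta, U, z, z, z, z, params, ratios)
  if (any(Re(eq$coef$energy) <= 0)) {
    stop("degenerate conductivity: 1 + beta*theta must stay positive")
  }
  unname(-eq$energy / eq$coef$energy)
}

#' Bacterial-density equation solved for `chi''`
#' @inheritParams momentum_rhs
#' @return value(s) of `chi''`
#' @export
bacteria_rhs <- function(eta, state, params, ratios = unit_ratios()) {
  U <- .as_state(state)
  z <- rep(0, length(eta))
  eq <- .eq_residuals(eta, U, z, z, z, z, params, ratios)
  unname(-eq$bact)
}

# First-order form of the full 10-component system, vectorized over nodes.
.flow_system_rhs <- function(eta, U, params, ratios) {
  z <- rep(0, length(eta))
  eq <- .eq_residuals(eta, U, z, z, z, z, params, ratios)
  gpp <- -eq$micro / eq$coef$micro
  out <- U * 0
  out["f", ]      <- U["fp", ]
  out["fp", ]     <- U["fpp", ]
  out["fpp", ]    <- U["fppp", ]
  out["fppp", ]   <- -(eq$mom - params$K1 * gpp) / eq$coef$mom
  out["g", ]      <- U["gp", ]
  out["gp", ]     <- gpp
  out["theta", ]  <- U["thetap", ]
  out["thetap", ] <- -eq$energy / eq$coef$energy
  out["chi", ]    <- U["chip", ]
  out["chip", ]   <- -eq$bact
  out
}

#' Boundary-condition residuals
#'
#' Wall (`eta = 0`): `f = 0`, `f' = 1`, `theta = 1`, `chi = 1`,
#' `g + m0 f'' = 0`.  Far field (`eta = eta_inf`): `f' = f'' = theta =
#' chi = g = 0`.  A converged profile satisfies all ten to solver tolerance.
#'
#' @param state_at_0,state_at_inf 10-component state vectors at the wall and
#'   at the truncation point
#' @param params a [flow_params] object
#' @return numeric residual vector of length 10
#' @export
boundary_residuals <- function(state_at_0, state_at_inf, params) {
  a <- .as_state(state_at_0)[, 1]
  b <- .as_state(state_at_inf)[, 1]
  c(f0      = a[["f"]],
    fp0     = a[["fp"]] - 1,
    theta0  = a[["theta"]] - 1,
    chi0    = a[["chi"]] - 1,
    g0      = a[["g"]] + params$m0 * a[["fpp"]],
    fpInf   = b[["fp"]],
    fppInf  = b[["fpp"]],
    thetaInf = b[["theta"]],
    chiInf  = b[["chi"]],
    gInf    = b[["g"]])
}

#' Recover the pressure field from a converged profile
#'
#' Evaluates the algebraic pressure expression pointwise from the profile's
#' derivatives:
#' `P = (mu_r + K1 + alpha1)(f''' + f''/(eta+K) - f'/(eta+K)^2)
#'    + (rho_r/2)(f f'' - f'^2 + f f'/(eta+K))
#'    - ((eta+K)/K)(gamma eta/2)(f'' + f')
#'    - ((eta+K)/(2K))(sigma_r M + rho_r beta0) f'
#'    + alpha2 (f'' + f'/(eta+K))^2 (f''' + f''/(eta+K) - f'/(eta+K)^2)`.
#'
#' @param profile an `hnf_profile` from [solve_flow], or a list with fields
#'   `eta`, `states`, `params`, `ratios`
#' @return numeric vector `P(eta)` on the profile grid
#' @export
recover_pressure <- function(profile) {
  p <- profile$params; r <- profile$ratios
  eta <- profile$eta; U <- profile$states
  cv <- .curv(eta, p$K); iv <- cv$inv; kr <- cv$kr
  f <- U["f", ]; fp <- U["fp", ]; fpp <- U["fpp", ]; fppp <- U["fppp", ]
  S1 <- fpp + fp * iv
  G <- fppp + fpp * iv - fp * iv^2
  (r$mu_r + p$K1 + p$alpha1) * G +
    0.5 * r$rho_r * (f * fpp - fp^2 + f * fp * iv) -
    (1 / kr) * (p$gamma * eta / 2) * (fpp + fp) -
    (1 / (2 * kr)) * (r$sigma_r * p$M + r$rho_r * p$beta0) * fp +
    p$alpha2 * S1^2 * G
}
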