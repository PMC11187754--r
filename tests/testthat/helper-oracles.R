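# Independent oracles: direct transcriptions of the four similarity
# equations and the pressure expression, written as straight-line formulas
# (no shared code with the package's rearranged right-hand sides).  Feeding
# a package rhs output back into these pins down the algebraic
# rearrangement to round-off.

oracle_curv <- function(eta, K) {
  if (is.infinite(K)) list(iv = 0 * eta, kr = 1 + 0 * eta)
  else list(iv = 1 / (eta + K), kr = K / (eta + K))
}

# Full momentum residual, fiv supplied explicitly.
oracle_momentum <- function(eta, s, fiv, p, r) {
  cv <- oracle_curv(eta, p$K); iv <- cv$iv; kr <- cv$kr
  S <- s$fpp + s$fp * iv
  (r$mu_r + p$K1 + p$alpha1) *
    (fiv + 2 * s$fppp * iv - s$fpp * iv^2 + s$fp * iv^3) -
    (r$sigma_r * p$M + r$mu_r * p$beta0) * S -
    p$alpha2 * (S^2 * fiv +
                  (s$fpp^2 - 3 * s$fp * s$fpp * iv - s$fp^2 * iv^2) * s$fpp * iv^2 +
                  3 * s$fp^3 * iv^5 +
                  2 * S * s$fppp^2 +
                  2 * (3 * s$fpp^2 + 2 * s$fp * s$fpp * iv - s$fp^2 * iv^2) *
                    s$fppp * iv) -
    p$K1 * (s$gpp + s$gp * iv) +
    r$rho_r * (kr * (s$f * s$fppp - s$fp * s$fpp) +
                 kr * iv * (s$f * s$fpp - s$fp^2) -
                 kr * iv^2 * s$f * s$fp) -
    p$gamma * (eta / 2 * s$fppp + 3 / 2 * s$fpp +
                 (eta / 2 * s$fpp + s$fp) * iv)
}

oracle_microrotation <- function(eta, s, gpp, p, r) {
  cv <- oracle_curv(eta, p$K); iv <- cv$iv; kr <- cv$kr
  (r$mu_r + p$K1 / 2) * (gpp + s$gp * iv) +
    kr * (s$f * s$gp - s$fp * s$g) -
    p$K1 * (2 * s$g + s$fpp + s$fp * iv) -
    p$gamma / 2 * (eta * s$gp + 3 * s$g)
}

oracle_energy <- function(eta, s, thetapp, p, r) {
  cv <- oracle_curv(eta, p$K); iv <- cv$iv; kr <- cv$kr
  r$k_r * ((1 + p$beta * s$theta) * (thetapp + s$thetap * iv) +
             p$beta * s$thetap^2) +
    r$sigma_r * p$M * p$Pr * p$Ec * s$fp^2 +
    r$rhocp_r * p$Pr * (kr * s$f - p$gamma * eta / 2) * s$thetap +
    p$Pr * p$Q * s$theta
}

oracle_bacteria <- function(eta, s, chipp, p, r) {
  cv <- oracle_curv(eta, p$K); iv <- cv$iv; kr <- cv$kr
  chipp + s$chip * iv +
    p$Lb * (kr * s$f - p$gamma * eta / 2) * s$chip +
    p$lam * (p$Omega + s$chi)
}

oracle_pressure <- function(eta, s, p, r) {
  cv <- oracle_curv(eta, p$K); iv <- cv$iv; kr <- cv$kr
  S <- s$fpp + s$fp * iv
  G <- s$fppp + s$fpp * iv - s$fp * iv^2
  (r$mu_r + p$K1 + p$alpha1) * G +
    0.5 * r$rho_r * (s$f * s$fpp - s$fp^2 + s$f * s$fp * iv) -
    (1 / kr) * (p$gamma * eta / 2) * (s$fpp + s$fp) -
    (1 / (2 * kr)) * (r$sigma_r * p$M + r$rho_r * p$beta0) * s$fp +
    p$alpha2 * S^2 * G
}

# Random smooth state (named list) and parameter draws for property tests.
random_state <- function() {
  v <- stats::rnorm(14)
  names(v) <- c("f", "fp", "fpp", "fppp", "g", "gp", "theta", "thetap",
                "chi", "chip", "fiv", "gpp", "thetapp", "chipp")
  as.list(v)
}

random_params <- function() {
  flow_params(K = stats::runif(1, 0.5, 5),
              K1 = stats::runif(1, 0, 0.5),
              alpha1 = stats::runif(1, 0, 0.3),
              alpha2 = stats::runif(1, 0, 0.05),
              M = stats::runif(1, 0, 2),
              beta0 = stats::runif(1, 0, 1),
              gamma = stats::runif(1, 0, 0.5),
              beta = stats::runif(1, 0, 0.3),
              Ec = stats::runif(1, 0, 0.5),
              Pr = stats::runif(1, 0.5, 25),
              Lb = stats::runif(1, 0.05, 2),
              lam = stats::runif(1, 0, 0.5),
              Omega = stats::runif(1, 0, 0.5),
              m0 = stats::runif(1, 0, 1))
}

random_ratios <- function() {
  mixture_ratios(volume_fractions(stats::runif(1, 0, 0.05),
                                  stats::runif(1, 0, 0.05)))
}

state_vec <- function(s) {
  c(s$f, s$fp, s$fpp, s$fppp, s$g, s$gp, s$theta, s$thetap, s$chi, s$chip)
}

# Exact classical flat-sheet state (Crane for M = 0): f = (1 - e^{-m eta})/m,
# m = sqrt(1+M); theta/chi rest fields at zero targets.
crane_state <- function(eta, M = 0) {
  m <- sqrt(1 + M)
  e <- exp(-m * eta)
  U <- rbind(f = (1 - e) / m, fp = e, fpp = -m * e, fppp = m^2 * e,
             g = 0 * eta, gp = 0 * eta, theta = 0 * eta, thetap = 0 * eta,
             chi = 0 * eta, chip = 0 * eta)
  U
}
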