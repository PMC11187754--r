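test_that("rhs rearrangements satisfy the transcription oracles on random states", {
  set.seed(42)
  for (i in 1:100) {
    s <- random_state()
    p <- random_params()
    r <- random_ratios()
    eta <- stats::runif(1, 0.01, 10)
    sv <- state_vec(s)
    gpp <- microrotation_rhs(eta, sv, p, r)
    expect_lt(abs(oracle_microrotation(eta, s, gpp, p, r)), 1e-10)
    # the momentum equation couples to g'' through K1; back-substitute the
    # system-consistent value from the microrotation equation
    s$gpp <- gpp
    fiv <- momentum_rhs(eta, sv, p, r)
    expect_lt(abs(oracle_momentum(eta, s, fiv, p, r)), 1e-10)
    # keep 1 + beta*theta away from zero for the energy solve
    if (1 + p$beta * s$theta > 0.05) {
      thpp <- energy_rhs(eta, sv, p, r)
      expect_lt(abs(oracle_energy(eta, s, thpp, p, r)), 1e-10)
    }
    chpp <- bacteria_rhs(eta, sv, p, r)
    expect_lt(abs(oracle_bacteria(eta, s, chpp, p, r)), 1e-10)
  }
})

test_that("rhs functions are pure (bit-identical repeat calls)", {
  set.seed(7)
  s <- state_vec(random_state())
  p <- random_params(); r <- random_ratios()
  expect_identical(momentum_rhs(1.3, s, p, r), momentum_rhs(1.3, s, p, r))
  expect_identical(energy_rhs(1.3, s, p, r), energy_rhs(1.3, s, p, r))
})

test_that("rest state annihilates the reduced momentum operator", {
  p <- flow_params(K = 2, K1 = 0, alpha1 = 0, alpha2 = 0, M = 0, beta0 = 0,
                   gamma = 0, lam = 0)
  s <- rep(0, 10)
  expect_equal(momentum_rhs(1.0, s, p, unit_ratios()), 0)
  # K1 = 0 and g = 0: microrotation trivially satisfied
  expect_equal(microrotation_rhs(1.0, s, p, unit_ratios()), 0)
})

test_that("energy and bacteria reduce to trivial second derivatives", {
  p <- flow_params(Ec = 0, beta = 0, lam = 0, gamma = 0)
  s <- rep(0, 10); s[2] <- 0  # all fields zero
  expect_equal(energy_rhs(1.0, s, p, unit_ratios()), 0)
  expect_equal(bacteria_rhs(1.0, s, p, unit_ratios()), 0)
})

test_that("flat classical limit: momentum is the eta-derivative of the flat equation", {
  # With the closed form f = (1 - exp(-m eta))/m the third-order flat
  # equation holds exactly, hence so must its derivative, which is what the
  # fourth-order curved equation becomes at the flat sentinel.
  eta <- seq(0, 10, length.out = 41)
  for (M in c(0, 1, 3)) {
    p <- classical_limit_params(M)
    U <- crane_state(eta, M)
    fiv <- momentum_rhs(eta, U, p, unit_ratios())
    m <- sqrt(1 + M)
    expect_lt(max(abs(fiv - (-m^3 * exp(-m * eta)))), 1e-8)
    # and the full residual of the closed form is ~0
    s <- list(f = U["f", ], fp = U["fp", ], fpp = U["fpp", ],
              fppp = U["fppp", ], g = 0 * eta, gp = 0 * eta,
              theta = 0 * eta, thetap = 0 * eta, chi = 0 * eta,
              chip = 0 * eta, gpp = 0 * eta)
    expect_lt(max(abs(oracle_momentum(eta, s, -m^3 * exp(-m * eta), p,
                                      unit_ratios()))), 1e-8)
  }
})

test_that("boundary residuals vanish for exact states and flag violations", {
  eta_inf <- 15
  U0 <- crane_state(0, 0)
  # wall values: f=0, fp=1 from Crane; set theta/chi wall fields to 1
  U0["theta", 1] <- 1; U0["chi", 1] <- 1
  Uinf <- crane_state(eta_inf, 0) * 0
  p <- classical_limit_params(0)
  res <- boundary_residuals(U0[, 1], Uinf[, 1], p)
  expect_equal(max(abs(res)), 0)
  # far-field zeros give exactly zero far-field residuals even for junk wall
  res2 <- boundary_residuals(rnorm(10), rep(0, 10), p)
  expect_equal(unname(res2[6:10]), rep(0, 5))
  # m0 couples g(0) to f''(0)
  p2 <- flow_params(m0 = 0.5)
  st <- rep(0, 10); st[2] <- 1; st[7] <- 1; st[9] <- 1
  st[3] <- -2; st[5] <- 1  # f''(0) = -2, g(0) = 1
  expect_equal(unname(boundary_residuals(st, rep(0, 10), p2)["g0"]), 0)
})

test_that("pressure recovery matches the transcription oracle and rest state", {
  set.seed(11)
  eta <- seq(0, 12, length.out = 30)
  p <- random_params(); r <- random_ratios()
  U <- matrix(rnorm(10 * 30), 10, 30,
              dimnames = list(c("f", "fp", "fpp", "fppp", "g", "gp",
                                "theta", "thetap", "chi", "chip"), NULL))
  prof <- list(eta = eta, states = U, params = p, ratios = r)
  P <- recover_pressure(prof)
  s <- list(f = U["f", ], fp = U["fp", ], fpp = U["fpp", ],
            fppp = U["fppp", ])
  expect_equal(P, oracle_pressure(eta, s, p, r), tolerance = 1e-12)
  prof$states <- U * 0
  expect_equal(recover_pressure(prof), rep(0, 30))
})

test_that("pressure gradient is consistent with the radial-momentum relation", {
  # On a converged profile, dP/deta from finite differences of the
  # recovered P must track the derivative of the recovered pressure's own
  # spline to discretization accuracy (smoothness/consistency check).
  prof <- solve_flow(classical_limit_params(1))
  P <- recover_pressure(prof)
  dP <- stats::splinefun(prof$eta, P)(prof$eta, deriv = 1)
  mid <- 2:(length(prof$eta) - 1)
  fd <- (P[mid + 1] - P[mid - 1]) / (prof$eta[mid + 1] - prof$eta[mid - 1])
  expect_lt(max(abs(fd - dP[mid])), 1e-3)
})

test_that("dimensionless group conversion honours the similarity scalings", {
  bf <- material("blood")
  sc <- dimensional_scenario(a = 2, c = 0.2, t = 1, s = 0.1, R = 0.01,
                             B0 = 0.5, k1 = 1e-8, beta1 = 2, c1 = 3,
                             Dn = 1e-7, lam0 = 0.1, nu_f = 2.7e-6,
                             fluid = bf, deltaT = 10)
  p <- dimensionless_groups(sc)
  fac <- 1 - 0.2
  expect_equal(p$K, 0.01 * sqrt(2 / (2.7e-6 * fac)))
  expect_equal(p$M, bf$sigma * 0.25 / (bf$rho * 2))
  expect_equal(p$beta0, (2.7e-6 * bf$rho) * fac / (bf$rho * 1e-8 * 2))
  expect_equal(p$gamma, 0.1)
  expect_equal(p$Lb, 2.7e-6 / 1e-7)
  expect_equal(p$lam, 0.1 / (2 * fac))
  expect_equal(p$Ec, (2 * 0.1 / fac)^2 / (bf$cp * 10))
  # B0 = 0 gives M = 0; steady limit gives gamma = 0 and K = R sqrt(a/nu)
  p0 <- dimensionless_groups(dimensional_scenario(a = 2, R = 0.01))
  expect_equal(p0$M, 0)
  expect_equal(p0$gamma, 0)
  expect_equal(p0$K, 0.01 * sqrt(2 / 2.7e-6))
  # blood constants give Pr near the standard blood value
  expect_equal(p$Pr, 2.7e-6 * bf$rho * bf$cp / bf$k)
  expect_gt(p$Pr, 10); expect_lt(p$Pr, 40)
  # similarity breakdown
  expect_error(dimensional_scenario(a = 1, c = 1, t = 1.2), "c\\*t")
})

test_that("flow parameter JSON round-trip rejects unknown keys", {
  p <- flow_params(M = 0.7, K = Inf)
  f <- withr::local_tempfile(fileext = ".json")
  flow_params_to_json(p, f)
  p2 <- flow_params_from_json(f)
  expect_equal(unclass(p2), unclass(p))
  writeLines('{"M": 1, "warp_factor": 9}', f)
  expect_error(flow_params_from_json(f), "unknown flow parameter")
})

test_that("parameter invariants are enforced", {
  expect_error(flow_params(K = 0), "K must be")
  expect_error(flow_params(M = -1), ">= 0")
  expect_error(flow_params(m0 = 2), "m0")
  expect_error(flow_params(Pr = 0), "Pr")
})
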