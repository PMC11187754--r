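# The frozen value -1.418681181 below was computed by an independent
# symbolic (exact rational) implementation of the order-12 recursion with
# L_f = f''' - f', f0 = 1 - e^-eta, hbar = 1/2, M = 1, evaluated to 10
# significant digits.  It pins the whole deformation pipeline (order
# extraction, resonant L-inverses, boundary constants) to the pen-and-paper
# algebra.
SYMBOLIC_FPP0_M1_HB05_ORD12 <- -1.418681181

test_that("basis-path HAM reproduces the exact symbolic recursion", {
  h <- ham_solve(classical_limit_params(1),
                 config = ham_config(order = 12, hbar_f = 0.5, hbar_g = 0.5,
                                     hbar_theta = 0.1, hbar_chi = 0.3),
                 on_divergence = "continue")
  expect_lt(abs(h$partial_sum$f["d2", 1] - SYMBOLIC_FPP0_M1_HB05_ORD12), 1e-6)
})

test_that("HAM converges to the classical M=1 benchmark at plateau hbar", {
  h <- ham_solve(classical_limit_params(1),
                 config = ham_config(order = 25, hbar_f = 0.3, hbar_g = -1,
                                     hbar_theta = 0.1, hbar_chi = 0.3),
                 on_divergence = "continue")
  expect_lt(abs(-h$partial_sum$f["d2", 1] - sqrt(2)), 1e-3)
})

test_that("initial guesses honour the printed forms and the wall condition", {
  eta <- seq(0, 15, length.out = 51)
  p0 <- flow_params(m0 = 0)
  g0 <- ham_initial_guess(eta, p0)
  expect_equal(unname(g0$f["d1", 1]), 1)              # f0'(0) = 1
  expect_equal(unname(g0$theta["d0", 1]), 1)          # theta0(0) = 1
  expect_lt(g0$theta["d0", length(eta)], 1e-6)
  expect_true(all(g0$g == 0))                 # m0 = 0 => g0 == 0
  p5 <- flow_params(m0 = 0.5)
  g5 <- ham_initial_guess(eta, p5)
  expect_equal(unname(g5$g["d0", 1]), unname(-0.5 * g5$f["d2", 1]))
})

test_that("auxiliary linear operators annihilate their kernels", {
  eta <- seq(0, 3, length.out = 1201)
  ker_f <- 2 + 0.7 * exp(-eta) - 0.3 * exp(eta)
  vf <- apply_linear_operator(ker_f, "f", eta)
  expect_lt(max(abs(vf[50:1150])), 1e-3 * max(abs(ker_f)))
  ker_g <- exp(-eta)
  vg <- apply_linear_operator(ker_g, "g", eta)
  expect_lt(max(abs(vg[50:1150])), 1e-6)
  # non-kernel input is not annihilated
  vs <- apply_linear_operator(sin(eta), "theta", eta)
  expect_gt(max(abs(vs)), 0.5)
})

test_that("fixed point: an exact seed produces a vanishing first order", {
  M <- 0
  p <- classical_limit_params(M)
  eta <- seq(0, 15, length.out = 201)
  e <- exp(-eta)
  seed <- list(f = rbind(d0 = 1 - e, d1 = e, d2 = -e, d3 = e, d4 = -e),
               g = rbind(d0 = 0 * eta, d1 = 0 * eta, d2 = 0 * eta),
               theta = rbind(d0 = e, d1 = -e, d2 = e),
               chi = rbind(d0 = e, d1 = -e, d2 = e))
  # at M=0 Crane's solution makes the momentum operator vanish exactly;
  # theta/chi seeds are not exact, so only the f component is pinned
  h <- ham_solve(p, config = ham_config(order = 1, n_nodes = 201),
                 seed_state = seed, on_divergence = "continue")
  expect_lt(max(abs(h$components[[2]]$f["d0", ])), 1e-8)
})

test_that("partial sums equal the elementwise sum of components", {
  h <- ham_solve(classical_limit_params(1),
                 config = ham_config(order = 4, hbar_f = 0.4, hbar_g = -1,
                                     hbar_theta = 0.1, hbar_chi = 0.3),
                 on_divergence = "continue")
  manual <- Reduce(`+`, lapply(h$components, `[[`, "f"))
  expect_equal(h$partial_sum$f, manual, tolerance = 1e-12)
  expect_equal(h$order_used, 4L)
})

test_that("HAM runs are deterministic", {
  cfg <- ham_config(order = 5, hbar_f = 0.4)
  a <- ham_solve(classical_limit_params(1), config = cfg,
                 on_divergence = "continue")
  b <- ham_solve(classical_limit_params(1), config = cfg,
                 on_divergence = "continue")
  expect_identical(a$partial_sum, b$partial_sum)
})

test_that("divergence is detected and reported at hostile hbar", {
  expect_error(
    ham_solve(classical_limit_params(1),
              config = ham_config(order = 12, hbar_f = -1, hbar_g = -1,
                                  hbar_theta = -1, hbar_chi = -1)),
    "re-select hbar")
})

test_that("hbar curve is flat for an exactly solved configuration", {
  # at M = 0 the initial guess solves the momentum equation exactly, so
  # f''(0) = -1 for every hbar: the whole curve is the plateau
  cv <- hbar_curve(classical_limit_params(0), quantity = "fpp0",
                   hbar_range = seq(-1, -0.2, by = 0.2), order = 5)
  expect_true(all(abs(cv$value + 1) < 1e-10))
  expect_true(all(is.finite(cv$value)))
})

test_that("hbar plateau selection picks the flattest region", {
  cv <- data.frame(hbar = seq(-1, 1, by = 0.25),
                   value = c(8, 4, 2, 1.01, 1.0, 1.02, 2, 4, 9))
  expect_equal(hbar_plateau(cv), 0)
})

test_that("comparison tables mirror the validation layout", {
  pv <- ham_validation_params()
  h <- ham_solve(pv, config = ham_config(order = 6, hbar_f = 0.4,
                                         hbar_g = -1, hbar_theta = -0.5,
                                         hbar_chi = -0.5),
                 on_divergence = "continue")
  prof <- solve_flow(pv)
  cmp <- compare_with_collocation(h, prof, eta_max = 10)
  expect_named(cmp$tables, c("fp", "g", "theta", "chi"))
  t1 <- cmp$tables$fp
  expect_equal(t1$ham[1], 1, tolerance = 1e-9)        # f'(0) = 1 both
  expect_equal(t1$reference[1], 1, tolerance = 1e-8)
  expect_lt(t1$abs_error[1], 1e-8)
  expect_true(all(t1$abs_error >= 0 & is.finite(t1$abs_error)))
  expect_true(all(cmp$summary$max_abs_error >= cmp$summary$mean_abs_error))
})

test_that("deformation stepping extends a solution by one order", {
  cfg <- ham_config(order = 3, hbar_f = 0.4, hbar_g = -1,
                    hbar_theta = 0.1, hbar_chi = 0.3)
  h3 <- ham_solve(classical_limit_params(1), config = cfg,
                  on_divergence = "continue")
  h4 <- ham_deformation_step(h3)
  expect_equal(h4$order_used, 4L)
  expect_equal(length(h4$components), 5L)
  # the first 4 components agree with the order-3 run
  expect_equal(h4$components[[4]]$f, h3$components[[4]]$f, tolerance = 1e-10)
})
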