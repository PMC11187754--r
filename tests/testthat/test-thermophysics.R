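test_that("mixture ratios reduce to 1 for the pure base fluid", {
  r <- mixture_ratios(volume_fractions(0, 0))
  expect_equal(unlist(unclass(r)),
               c(mu_r = 1, rho_r = 1, rhocp_r = 1, k_r = 1, sigma_r = 1))
})

test_that("viscosity ratio matches direct arithmetic and is increasing", {
  expect_equal(viscosity_ratio(volume_fractions(0.05, 0.05)), 0.9^(-2.5))
  expect_equal(viscosity_ratio(volume_fractions(0.1, 0.1)), 0.8^(-2.5))
  phis <- seq(0, 0.45, by = 0.05)
  vals <- vapply(phis, function(p) viscosity_ratio(c(p, p)), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("linear mixture rules match hand arithmetic and are exactly linear", {
  au <- material("Au"); ti <- material("TiO2"); bf <- material("blood")
  expect_equal(density_ratio(c(0.01, 0.01), au, ti, bf),
               0.01 * 19300 / 1063 + 0.01 * 686.20 / 1063 + 0.98)
  expect_equal(heat_capacity_ratio(c(0.01, 0.01), au, ti, bf),
               0.01 * (19300 * 129) / (1063 * 3594) +
                 0.01 * (686.20 * 4250) / (1063 * 3594) + 0.98)
  # equal-density particle leaves the ratio at 1
  p_eq <- particle_properties(cp = bf$cp, k = 1, sigma = 1, rho = bf$rho)
  expect_equal(density_ratio(c(0.02, 0), p_eq, ti, bf), 1)
  # second finite difference in each fraction is 0 (exact linearity)
  f <- function(p1v) density_ratio(c(p1v, 0.03), au, ti, bf)
  expect_equal(f(0.01) - 2 * f(0.02) + f(0.03), 0, tolerance = 1e-14)
  g <- function(p2v) heat_capacity_ratio(c(0.03, p2v), au, ti, bf)
  expect_equal(g(0.01) - 2 * g(0.02) + g(0.03), 0, tolerance = 1e-14)
})

test_that("Maxwell-type closures: limit, single-particle reduction, oracle", {
  au <- material("Au"); ti <- material("TiO2"); bf <- material("blood")
  # Phi -> 0 limit branch and continuity from above
  expect_identical(thermal_conductivity_ratio(c(0, 0), au, ti, bf), 1)
  # the closure approaches 1 with slope 3*(kbar - kb)/(kbar + 2 kb) <= 3,
  # so continuity holds at the O(Phi) level (3e-8 at Phi = 1e-8)
  expect_lt(abs(thermal_conductivity_ratio(c(5e-9, 5e-9), au, ti, bf) - 1),
            1e-7)
  expect_lt(abs(electrical_conductivity_ratio(c(5e-9, 5e-9), au, ti, bf) - 1),
            1e-7)
  expect_lt(abs(thermal_conductivity_ratio(c(5e-13, 5e-13), au, ti, bf) - 1),
            1e-11)
  # single particle reduces to the classical Maxwell form
  phi1 <- 0.03
  k1 <- au$k; kb <- bf$k
  classical <- (k1 + 2 * kb + 2 * phi1 * (k1 - kb)) /
    (k1 + 2 * kb - phi1 * (k1 - kb))
  expect_equal(thermal_conductivity_ratio(c(phi1, 0), au, ti, bf), classical)
  # independent substitution oracle at (0.01, 0.01)
  direct <- function(p1v, p2v, k1, k2, kb) {
    Phi <- p1v + p2v
    kbar <- (p1v * k1 + p2v * k2) / Phi
    (kbar + 2 * kb + 2 * (p1v * k1 + p2v * k2) - 2 * Phi * kb) /
      (kbar + 2 * kb - (p1v * k1 + p2v * k2) + Phi * kb)
  }
  expect_equal(thermal_conductivity_ratio(c(0.01, 0.01), au, ti, bf),
               direct(0.01, 0.01, au$k, ti$k, bf$k))
  expect_equal(electrical_conductivity_ratio(c(0.01, 0.01), au, ti, bf),
               direct(0.01, 0.01, au$sigma, ti$sigma, bf$sigma))
})

test_that("compute_all bundles components and is particle-order symmetric", {
  au <- material("Au"); ti <- material("TiO2"); bf <- material("blood")
  fr <- volume_fractions(0.01, 0.02)
  r <- compute_all(fr, au, ti, bf)
  expect_s3_class(r, "mixture_ratios")
  expect_equal(r$mu_r, viscosity_ratio(fr))
  expect_equal(r$rho_r, density_ratio(fr, au, ti, bf))
  expect_equal(r$rhocp_r, heat_capacity_ratio(fr, au, ti, bf))
  expect_equal(r$k_r, thermal_conductivity_ratio(fr, au, ti, bf))
  expect_equal(r$sigma_r, electrical_conductivity_ratio(fr, au, ti, bf))
  # swap particles with swapped fractions
  r2 <- compute_all(volume_fractions(0.02, 0.01), ti, au, bf)
  expect_equal(unclass(r2), unclass(r))
})

test_that("invalid inputs are rejected", {
  expect_error(volume_fractions(0.6, 0.4), "unphysical")
  expect_error(volume_fractions(-0.01, 0), "non-negative")
  expect_error(particle_properties(1, 1, 0, 1), "strictly positive")
  expect_error(material("adamantium"), "unknown material")
})

test_that("user materials load from JSON", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"name":"Cu","cp":385,"k":401,"sigma":5.96e7,"rho":8933}', f)
  m <- load_material(f)
  expect_equal(m$k, 401)
  expect_equal(m$name, "Cu")
})
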