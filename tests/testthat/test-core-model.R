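params <- oxygen_params()

test_that("consumption rates from the three benchmark diffusion limits", {
  # frozen benchmark triple (verified by direct arithmetic a = 6*D*p_o/(Omega*r_l^2))
  expect_equal(signif(estimate_consumption(233e-6, params)$a_volumetric, 3), 7.29e-7)
  expect_equal(signif(estimate_consumption(211e-6, params)$a_volumetric, 3), 8.89e-7)
  expect_equal(signif(estimate_consumption(255e-6, params)$a_volumetric, 3), 6.09e-7)
  # forward direction
  expect_equal(diffusion_limit(7.29e-7, params) * 1e6, 233, tolerance = 1e-3)
  expect_equal(diffusion_limit(6.09e-7, params) * 1e6, 255, tolerance = 1e-3)
  # definition: a chosen so 6*D*p_o/(a*Omega) = 1 m^2 gives r_l = 1 m
  a_unit <- 6 * params$D * params$p_o / params$Omega
  expect_equal(diffusion_limit(a_unit, params), 1)
  # invalid parameters
  expect_error(diffusion_limit(0, params), class = "spheroido2_invalid")
  expect_error(diffusion_limit(-1e-7, params), class = "spheroido2_invalid")
  expect_error(estimate_consumption(0, params), class = "spheroido2_invalid")
})

test_that("diffusion limit and consumption rate are exact inverses", {
  a_grid <- 10^seq(-8, -5, length.out = 13)
  for (a in a_grid) {
    back <- estimate_consumption(diffusion_limit(a, params), params)$a_volumetric
    expect_equal(back, a, tolerance = 1e-12)
  }
  # monotone sensitivity: halving a scales r_l by sqrt(2)
  expect_equal(diffusion_limit(3.645e-7, params) / diffusion_limit(7.29e-7, params),
               sqrt(2), tolerance = 1e-12)
})

test_that("characteristic cubic: bracketing, root, and benchmark value", {
  set.seed(42)
  for (i in 1:25) {
    r_l <- runif(1, 50e-6, 400e-6)
    r_o <- r_l * runif(1, 1.001, 6)
    cubic <- spheroidO2:::characteristic_cubic
    expect_gt(cubic(0, r_o, r_l), 0)
    expect_lt(cubic(r_o, r_o, r_l), 0)
    g <- solve_anoxic_radius(r_o, r_l)
    expect_gt(g$r_n, 0)
    expect_lt(g$r_n, r_o)
    # independent bisection oracle on the cubic, tolerance 1e-6 um
    rn_oracle <- bisection_root(function(x) cubic(x, r_o, r_l), 0, r_o,
                                tol = 1e-13)
    expect_equal(g$r_n, rn_oracle, tolerance = 1e-7)
    expect_equal(g$r_c, r_o - g$r_n)
  }
  # frozen benchmark: r_o = 300 um, r_l = 233 um -> r_n = 129.2 um
  g <- solve_anoxic_radius(300e-6, 233e-6)
  expect_equal(g$r_n * 1e6, 129.2249, tolerance = 1e-6)
  # at the limit: no core
  expect_identical(solve_anoxic_radius(233e-6, 233e-6)$r_n, 0)
  expect_identical(solve_anoxic_radius(150e-6, 233e-6)$r_n, 0)
  expect_equal(solve_anoxic_radius(150e-6, 233e-6)$r_c, 150e-6)
})

test_that("viable rim decreases monotonically towards the rim limit", {
  r_l <- 233e-6
  expect_equal(rim_limit(r_l), r_l / sqrt(3))
  expect_equal(rim_limit(233e-6) * 1e6, 134.5, tolerance = 1e-3)
  expect_equal(rim_limit(sqrt(3)), 1)
  expect_equal(rim_limit(2 * r_l), 2 * rim_limit(r_l))
  # r_c(r_l) = r_l; strictly decreasing for r_o > r_l; asymptote
  r_os <- r_l * c(1, 1.2, 1.7, 2.5, 4, 10, 30, 100)
  r_cs <- vapply(r_os, function(ro) solve_anoxic_radius(ro, r_l)$r_c, numeric(1))
  expect_equal(r_cs[1], r_l)
  expect_true(all(diff(r_cs) < 0))
  expect_true(all(r_cs[-1] > rim_limit(r_l)))
  # convergence is O(1/r_o): ~2% at 10 r_l, ~0.2% at 100 r_l (both verified
  # against the bisection oracle above)
  err10 <- solve_anoxic_radius(10 * r_l, r_l)$r_c / rim_limit(r_l) - 1
  err100 <- solve_anoxic_radius(100 * r_l, r_l)$r_c / rim_limit(r_l) - 1
  expect_lt(err10, 0.03)
  expect_lt(err100, 0.01)
  expect_lt(err100, err10 / 5)
})

test_that("boundary measurements invert the cubic (round trip)", {
  set.seed(7)
  for (i in 1:20) {
    r_l <- runif(1, 100e-6, 350e-6)
    r_o <- r_l * runif(1, 1.0001, 4)
    g <- solve_anoxic_radius(r_o, r_l)
    expect_equal(estimate_rl_from_boundaries(r_o, g$r_n), r_l,
                 tolerance = 1e-9)
  }
  expect_equal(estimate_rl_from_boundaries(300e-6, 0), 300e-6)
  expect_equal(estimate_rl_from_boundaries(300e-6, 129.2249e-6) * 1e6, 233,
               tolerance = 1e-6)
  expect_error(estimate_rl_from_boundaries(300e-6, 300e-6),
               class = "spheroido2_invalid")
  # continuity as r_n -> r_o: r_l approaches 0 smoothly (no jumps)
  r_o <- 300e-6
  rl_sweep <- vapply(r_o * seq(0.90, 0.9999, length.out = 40),
                     function(rn) estimate_rl_from_boundaries(r_o, rn),
                     numeric(1))
  expect_true(all(diff(rl_sweep) < 0))
  expect_true(all(abs(diff(rl_sweep)) < 25e-6))
})

test_that("partial pressure: boundary conditions and finite-difference oracle", {
  g <- solve_anoxic_radius(300e-6, 233e-6)
  a <- estimate_consumption(233e-6, params)$a_volumetric
  # surface and core boundary conditions
  expect_equal(partial_pressure(g$r_o, g, params), params$p_o)
  expect_equal(partial_pressure(g$r_n, g, params), 0)
  expect_equal(partial_pressure(g$r_n / 2, g, params), 0)
  expect_equal(partial_pressure(0, g, params), 0)
  # zero gradient just outside the core: the finite-difference slope there
  # is curvature-limited (O(h)), vanishingly small next to the surface slope
  h <- 1e-9
  slope_core <- partial_pressure(g$r_n + h, g, params) / h
  slope_surf <- (partial_pressure(g$r_o, g, params) -
                 partial_pressure(g$r_o - h, g, params)) / h
  expect_lt(abs(slope_core), 1e-4 * abs(slope_surf))
  # non-decreasing profile
  r <- seq(0, g$r_o, length.out = 500)
  p <- partial_pressure(r, g, params)
  expect_true(all(diff(p) >= -1e-12))
  # agreement with the FD oracle over the oxygenated region
  orc <- fd_pressure_oracle(g$r_o, g$r_n, a, params)
  p_pkg <- partial_pressure(orc$r, g, params)
  expect_lt(max(abs(p_pkg - orc$p)), 0.1)
  # spot value at r = 250 um against the oracle
  i250 <- which.min(abs(orc$r - 250e-6))
  expect_equal(partial_pressure(orc$r[i250], g, params), orc$p[i250],
               tolerance = 0.1 / 100)
  # domain errors
  expect_error(partial_pressure(-1e-6, g, params), class = "spheroido2_invalid")
  expect_error(partial_pressure(301e-6, g, params), class = "spheroido2_invalid")
})

test_that("partial pressure without a core matches the symmetric solution", {
  g <- solve_anoxic_radius(200e-6, 233e-6)
  a <- estimate_consumption(233e-6, params)$a_volumetric
  k <- a * params$Omega / (6 * params$D)
  expect_equal(partial_pressure(0, g, params, a), params$p_o - k * g$r_o^2)
  expect_equal(partial_pressure(g$r_o, g, params, a), params$p_o)
  orc <- fd_pressure_oracle(g$r_o, 0, a, params)
  expect_lt(max(abs(partial_pressure(orc$r, g, params, a) - orc$p)), 0.1)
})

test_that("isobar radius inverts the pressure profile", {
  g <- solve_anoxic_radius(300e-6, 233e-6)
  expect_equal(isobar_radius(0, g, params), g$r_n)
  expect_equal(isobar_radius(params$p_o, g, params), g$r_o)
  # against a bisection inversion of partial_pressure, within 1e-3 um
  r10_oracle <- bisection_root(
    function(r) partial_pressure(r, g, params) - 10, g$r_n, g$r_o)
  expect_equal(isobar_radius(10, g, params), r10_oracle, tolerance = 1e-6)
  # strictly increasing in p
  ps <- seq(0.5, 99.5, length.out = 30)
  rs <- isobar_radius(ps, g, params)
  expect_true(all(diff(rs) > 0))
  # round trip through partial_pressure
  expect_equal(partial_pressure(isobar_radius(37, g, params), g, params), 37,
               tolerance = 1e-9)
  expect_error(isobar_radius(-1, g, params), class = "spheroido2_invalid")
  expect_error(isobar_radius(101, g, params), class = "spheroido2_invalid")
  # sub-limit spheroid: pressures below the central pressure have no isobar
  g2 <- solve_anoxic_radius(200e-6, 233e-6)
  expect_warning(r_na <- isobar_radius(5, g2, params), "no isobar")
  expect_true(is.na(r_na))
  expect_equal(partial_pressure(isobar_radius(50, g2, params), g2, params), 50,
               tolerance = 1e-9)
})

test_that("oxygen profile container satisfies its invariants", {
  g <- solve_anoxic_radius(400e-6, 233e-6)
  pr <- oxygen_profile(g, params, n = 301)
  expect_equal(nrow(pr), 301)
  expect_equal(pr$radius_m[1], 0)
  expect_equal(pr$radius_m[301], g$r_o)
  expect_true(all(pr$pO2_mmHg[pr$radius_m <= g$r_n] == 0))
  expect_true(all(diff(pr$pO2_mmHg) >= -1e-12))
  expect_equal(pr$pO2_mmHg[301], params$p_o)
})
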