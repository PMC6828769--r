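# Frozen expected values below were computed with the independent oracles:
# adaptive ODE integration (rtol 1e-13) of p0'' = xi^2 p0 from the inlet
# conditions, plus quadrature of the velocity profile.

test_that("xi_parameter matches direct arithmetic and rejects bad input", {
  expect_identical(xi_parameter(0, 0.1), 0)
  expect_equal(xi_parameter(0.16, 0.1), 0.66057826, tolerance = 1e-8)
  expect_equal(xi_parameter(0.3, 0), 0.94868330, tolerance = 1e-8)
  expect_error(xi_parameter(-0.1, 0), ">= 0")
  expect_error(xi_parameter(0.1, -1), ">= 0")
})

test_that("perturbation coefficients encode the inlet conditions exactly", {
  co <- perturbation_coefficients(channel_groups(lambda2 = 0))
  expect_equal(co$C1, 2.53215353, tolerance = 1e-8)
  expect_equal(co$C2, 0.46784647, tolerance = 1e-8)
  for (g in list(channel_groups(), channel_groups(5, 0.02, 700, 1.2, 0.05),
                 rp_groups(K = 6.23e-4))) {
    co <- perturbation_coefficients(g)
    l1 <- g$lambda1
    expect_equal(co$C1 + co$C2, g$p_i, tolerance = 1e-14)
    expect_equal(g$xi * (co$C2 - co$C1), -3 / (2 * g$A * (1 + l1)),
                 tolerance = 1e-14)
    expect_equal(co$alpha, (2 / 15) * g$xi^2 * (1 + l1), tolerance = 1e-15)
    # first-order inlet conditions (derived mode): p1(0) = 0 and the slope
    # condition from the zero net inlet flow correction
    expect_equal(co$C3 + co$C4 + co$alpha * (co$C1^2 + co$C2^2), 0,
                 tolerance = 1e-12 * max(1, abs(co$C3)))
    expect_equal(
      g$xi * (co$C4 - co$C3) +
        2 * g$xi * co$alpha * (co$C2^2 - co$C1^2),
      -(1 + l1) * g$xi^4 * g$p_i / (10 * g$A * g$K),
      tolerance = 1e-12 * max(1, abs(co$C3))
    )
  }
  # the as-printed C3 violates the zero inlet-pressure-correction condition
  cp <- perturbation_coefficients(channel_groups(), c3_mode = "as_printed")
  expect_gt(abs(cp$C3 + cp$C4 + cp$alpha * (cp$C1^2 + cp$C2^2)), 0.1)
  expect_error(perturbation_coefficients(channel_groups(K = 0)), "singular")
})

test_that("pressure matches the ODE oracle value and the limits", {
  fld <- flow_field(channel_groups(lambda2 = 0))
  expect_equal(pressure(fld, 0), 3, tolerance = 1e-14)
  expect_equal(pressure(fld, 0.5), 2.4708467167, tolerance = 1e-8)
  # impermeable limit: linear Poiseuille-type drop 3x/(2A(1+lambda1))
  f0 <- flow_field(dimensionless_groups(3, 0, 1, 0, 0))
  expect_equal(pressure(f0, 1), 1.5, tolerance = 1e-14)
  expect_equal(pressure(f0, c(0, 0.25, 1)), 3 - 1.5 * c(0, 0.25, 1),
               tolerance = 1e-14)
  expect_error(pressure(fld, 1.2), "\\[0, 1\\]")
  fx <- flow_field(channel_groups(), extrapolate = TRUE)
  expect_silent(pressure(fx, 1.2))
})

test_that("velocity components reproduce oracle values and conditions", {
  fld <- flow_field(channel_groups(lambda2 = 0))
  expect_equal(axial_velocity(fld, 0.3, 0), 0.5473589372, tolerance = 1e-8)
  expect_equal(normal_velocity(fld, 0.3, 1), 0.4235725246, tolerance = 1e-8)
  for (f in list(fld, flow_field(channel_groups()))) {
    xs <- seq(0, 1, by = 0.1)
    expect_equal(axial_velocity(f, xs, 1), rep(0, 11))       # no slip
    expect_equal(normal_velocity(f, xs, 0), rep(0, 11))      # centerline
    # Darcy wall condition, exact at the truncation order
    expect_equal(normal_velocity(f, xs, 1), f$groups$K * pressure(f, xs),
                 tolerance = 1e-14)
    # inlet normalization 2A * int_0^1 u(0,y) dy = 1
    qi <- stats::integrate(function(y) axial_velocity(f, 0, y), 0, 1,
                           rel.tol = 1e-12)$value
    expect_equal(2 * f$groups$A * qi, 1, tolerance = 1e-10)
  }
})

test_that("stress tensor is symmetric and reduces to the shear form", {
  set.seed(7)
  fld <- flow_field(channel_groups())
  xs <- runif(20, 0.05, 0.95)
  ys <- runif(20, -0.95, 0.95)
  s <- stress_components(fld, xs, ys, delta = 0.05)
  expect_identical(s$S_xy, s$S_yx)
  expect_equal(stress_components(fld, xs, 0)$S_xy, rep(0, 20),
               tolerance = 1e-14)
  # lambda2 = 0, delta = 0: S_xy = du/dy / (1 + lambda1), checked by finite
  # differences of the axial velocity
  f0 <- flow_field(channel_groups(lambda2 = 0))
  s0 <- stress_components(f0, xs, ys, delta = 0)
  uy <- vapply(seq_along(xs), function(i) {
    fd1(function(y) axial_velocity(f0, xs[i], y), ys[i])
  }, numeric(1))
  expect_equal(s0$S_xy, uy / 1.1, tolerance = 1e-8)
  expect_true(all(s0$S_xx == 0) && all(s0$S_yy == 0))  # delta factors
})

test_that("wall shear equals the negative pressure gradient", {
  f0 <- flow_field(channel_groups(lambda2 = 0))
  expect_equal(wall_shear(f0, 0), 1.3636363636, tolerance = 1e-8)
  xs <- seq(0.1, 0.9, by = 0.2)
  dpdx <- vapply(xs, function(x) fd1(function(z) pressure(f0, z), x),
                 numeric(1))
  expect_equal(wall_shear(f0, xs), -dpdx, tolerance = 1e-8)
  # the first-order retardation term cancels analytically: tau_w = -dp/dx
  f1 <- flow_field(channel_groups())
  dpdx1 <- vapply(xs, function(x) fd1(function(z) pressure(f1, z), x),
                  numeric(1))
  expect_equal(wall_shear(f1, xs), -dpdx1, tolerance = 1e-8)
  # impermeable wall: uniform shear along the channel
  fK0 <- flow_field(dimensionless_groups(3, 0, 1, 0.1, 0.03))
  expect_equal(diff(wall_shear(fK0, c(0.1, 0.5, 0.9))), c(0, 0))
})

test_that("flow rate is normalized, conserved at K = 0, and a quadrature", {
  for (f in list(flow_field(channel_groups()),
                 flow_field(channel_groups(), order = 0),
                 flow_field(channel_groups(2, 0.05, 40, 1.5, 0.05)))) {
    expect_equal(flow_rate(f, 0), 1, tolerance = 1e-13)
    for (x in c(0.17, 0.62, 1)) {
      q_quad <- f$groups$A *
        stats::integrate(function(y) axial_velocity(f, x, y), -1, 1,
                         rel.tol = 1e-12)$value
      expect_equal(flow_rate(f, x), q_quad, tolerance = 1e-10)
    }
  }
  fK0 <- flow_field(dimensionless_groups(3, 0, 1, 0.1, 0.03))
  expect_equal(flow_rate(fK0, seq(0, 1, by = 0.25)), rep(1, 5),
               tolerance = 1e-14)
})

test_that("leakage flux balances the flow-rate gradient and the seepage", {
  fld <- flow_field(channel_groups())
  xs <- seq(0.1, 0.9, by = 0.1)
  minus_dQ <- -vapply(xs, function(x) fd1(function(z) flow_rate(fld, z), x),
                      numeric(1))
  expect_equal(leakage_flux(fld, xs), minus_dQ, tolerance = 1e-8)
  # q = 2 A K p(x), exact at the truncation order
  expect_equal(leakage_flux(fld, xs),
               2 * fld$groups$A * fld$groups$K * pressure(fld, xs),
               tolerance = 1e-13)
  f0 <- flow_field(channel_groups(lambda2 = 0))
  expect_equal(leakage_flux(f0, xs),
               2 * f0$groups$A * f0$groups$K *
                 field_component(f0, "p0", xs),
               tolerance = 1e-13)
  fK0 <- flow_field(dimensionless_groups(3, 0, 1, 0.1, 0.03))
  expect_equal(leakage_flux(fK0, xs), rep(0, length(xs)))
})

test_that("fractional reabsorption matches the quadrature oracle", {
  expect_equal(fractional_reabsorption(flow_field(channel_groups(lambda2 = 0))),
               0.8051254024, tolerance = 1e-8)
  expect_identical(
    fractional_reabsorption(flow_field(dimensionless_groups(3, 0, 1, 0.1, 0))),
    0
  )
  fld <- flow_field(channel_groups())
  expect_equal(fractional_reabsorption(fld), 1 - flow_rate(fld, 1),
               tolerance = 1e-13)
})

test_that("mean pressure difference starts at zero and grows with x", {
  fld <- flow_field(channel_groups())
  expect_identical(mean_pressure_difference(fld, 0), 0)
  xs <- seq(0, 1, length.out = 50)
  dp <- mean_pressure_difference(fld, xs)
  q <- flow_rate(fld, xs)
  expect_true(all(diff(dp)[q[-50] > 0] >= 0))
})

test_that("stream function integrates the axial velocity", {
  fld <- flow_field(channel_groups())
  xs <- c(0.2, 0.5, 0.8)
  expect_equal(stream_function(fld, xs, 0), rep(0, 3))
  expect_equal(stream_function(fld, xs, 1),
               flow_rate(fld, xs) / (2 * fld$groups$A), tolerance = 1e-13)
  psi_quad <- stats::integrate(function(y) axial_velocity(fld, 0.5, y),
                               0, 0.7, rel.tol = 1e-12)$value
  expect_equal(stream_function(fld, 0.5, 0.7), psi_quad, tolerance = 1e-10)
})

test_that("the implicit streamline equation is constant along a contour", {
  fld <- flow_field(channel_groups())
  xs <- seq(0.05, 0.9, length.out = 40)
  # keep the level below the wall streamline everywhere so the contour
  # stays inside the channel over the whole x range
  level <- 0.4 * min(flow_rate(fld, xs)) / (2 * fld$groups$A)
  ys <- vapply(xs, function(x) {
    stats::uniroot(function(y) stream_function(fld, x, y) - level,
                   lower = 0, upper = 1, tol = 1e-13)$root
  }, numeric(1))
  C5 <- streamline_residual(fld, xs[1], ys[1], 0)
  resid <- streamline_residual(fld, xs, ys, C5)
  expect_lt(max(abs(resid)), 1e-8)
  # the residual is the stream function rescaled by 60/(1+lambda1)
  expect_equal(streamline_residual(fld, xs, ys, 0),
               60 / 1.1 * stream_function(fld, xs, ys), tolerance = 1e-13)
})

test_that("stagnation point appears exactly where the flow reverses", {
  # closed form at lambda2 = 0: x* = log(C1/C2) / (2 xi)
  stag0 <- function(p_i, K) {
    co <- perturbation_coefficients(
      dimensionless_groups(p_i, K, 1, 0.1, 0))
    log(co$C1 / co$C2) / (2 * co$xi)
  }
  expect_true(is.na(stagnation_point(flow_field(
    dimensionless_groups(3, 0.16, 1, 0.1, 0)))))  # root at x ~ 1.28 > 1
  expect_gt(stag0(3, 0.16), 1)
  expect_equal(stagnation_point(flow_field(
    dimensionless_groups(3, 0.25, 1, 0.1, 0))), stag0(3, 0.25),
    tolerance = 1e-9)
  expect_equal(stag0(3, 0.25), 0.74973397, tolerance = 1e-7)
  expect_equal(stagnation_point(flow_field(
    dimensionless_groups(4, 0.16, 1, 0.1, 0))), stag0(4, 0.16),
    tolerance = 1e-9)
  expect_equal(stag0(4, 0.16), 0.86436005, tolerance = 1e-7)
  # no stagnation for an impermeable wall
  expect_true(is.na(stagnation_point(flow_field(
    dimensionless_groups(3, 0, 1, 0.1, 0.03)))))
})
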