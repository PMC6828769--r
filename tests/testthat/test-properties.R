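# Property-style invariants over seeded random parameter sets spanning
# K in [1e-4, 0.3], p_i in [0.01, 5], A in [1, 2000], lambda1 in [0, 2],
# lambda2 in [0, 0.05].

fixture_fields <- function(n = 10) {
  ps <- generate_parameter_fixtures(n)
  lapply(seq_len(n), function(i) {
    flow_field(dimensionless_groups(ps$p_i[i], ps$K[i], ps$A[i],
                                    ps$lambda1[i], ps$lambda2[i]))
  })
}

test_that("boundary conditions hold at both truncation orders", {
  xs <- seq(0, 1, length.out = 21)
  for (fld in fixture_fields(10)) {
    for (ord in 0:1) {
      f <- flow_field(fld$groups, order = ord)
      expect_lt(max(abs(axial_velocity(f, xs, 1))), 1e-10)
      expect_lt(max(abs(normal_velocity(f, xs, 0))), 1e-10)
      # shear-free centerline: u is even in y, so a symmetric difference
      # across y = 0 vanishes identically
      expect_lt(max(abs(axial_velocity(f, xs, 1e-4) -
                          axial_velocity(f, xs, -1e-4))), 1e-12)
      scale <- max(1, abs(f$groups$K * pressure(f, xs)))
      expect_lt(max(abs(normal_velocity(f, xs, 1) -
                          f$groups$K * pressure(f, xs))) / scale, 1e-10)
    }
  }
})

test_that("mass is conserved: -dQ/dx = q(x) = 2A v(x, 1)", {
  xs <- seq(0.05, 0.95, length.out = 19)
  for (fld in fixture_fields(10)) {
    A <- fld$groups$A
    minus_dQ <- -vapply(xs, function(x) {
      fd1(function(z) flow_rate(fld, z), x, h = 1e-5)
    }, numeric(1))
    q <- leakage_flux(fld, xs)
    # FD truncation scales with A * p_i; normalize before comparing
    scale <- max(1, max(abs(q)))
    expect_lt(max(abs(minus_dQ - q)) / scale, 1e-8)
    expect_equal(q, 2 * A * normal_velocity(fld, xs, 1),
                 tolerance = 1e-12)
  }
  # at channel scale the absolute tolerance holds directly
  fld <- flow_field(channel_groups())
  minus_dQ <- -vapply(xs, function(x) {
    fd1(function(z) flow_rate(fld, z), x, h = 1e-5)
  }, numeric(1))
  expect_lt(max(abs(minus_dQ - leakage_flux(fld, xs))), 1e-8)
})

test_that("the velocity field is pointwise divergence-free", {
  pts_x <- seq(0.1, 0.9, length.out = 7)
  pts_y <- seq(-0.8, 0.8, length.out = 7)
  h <- 1e-4
  for (fld in fixture_fields(6)) {
    div <- outer(pts_x, pts_y, function(x, y) {
      (axial_velocity(fld, x + h, y) - axial_velocity(fld, x - h, y)) /
        (2 * h) +
        (normal_velocity(fld, x, y + h) - normal_velocity(fld, x, y - h)) /
          (2 * h)
    })
    expect_lt(max(abs(div)), 1e-6)
  }
})

test_that("fields have the correct parity and p is independent of y", {
  xs <- seq(0.1, 0.9, length.out = 5)
  ys <- c(0.2, 0.5, 0.9)
  for (fld in fixture_fields(6)) {
    for (y in ys) {
      expect_identical(axial_velocity(fld, xs, y),
                       axial_velocity(fld, xs, -y))
      expect_identical(normal_velocity(fld, xs, y),
                       -normal_velocity(fld, xs, -y))
    }
  }
})

test_that("closed-form pressures agree with the ODE oracle to 1e-8", {
  sets <- fixture_fields(6)
  sets <- c(sets, list(flow_field(rp_groups(K = 6.23e-4))))
  for (fld in sets) {
    or <- ode_oracle_pressure(fld$groups, order = 1,
                              rtol = 1e-12, atol = 1e-14)
    expect_lt(max(abs(field_component(fld, "p0", or$x) - or$p0)), 1e-8)
    expect_lt(max(abs(field_component(fld, "p1", or$x) - or$p1)), 1e-8)
  }
})

test_that("the two first-order forcing variants of the oracle agree", {
  g <- channel_groups()
  a <- ode_oracle_pressure(g, forcing = "analytic", rtol = 1e-12,
                           atol = 1e-14)
  s <- ode_oracle_pressure(g, forcing = "state", rtol = 1e-12, atol = 1e-14)
  expect_lt(max(abs(a$p1 - s$p1)), 1e-10)
})

test_that("Newtonian limit: parabolic profile, xi = sqrt(3K), no correction", {
  for (K in c(0.05, 0.16, 0.3)) {
    rep <- newtonian_limit_check(dimensionless_groups(3, K, 1, 0.7, 0.04))
    expect_true(rep$xi_ok)
    expect_lt(rep$parabolic_max_dev, 1e-12)
    expect_identical(rep$first_order_max, 0)
    expect_true(rep$pass)
  }
})

test_that("an order-0 field ignores lambda2 entirely", {
  g <- channel_groups(lambda2 = 0.05)
  f0 <- flow_field(g, order = 0)
  fz <- flow_field(channel_groups(lambda2 = 0))
  xs <- seq(0, 1, length.out = 11)
  expect_equal(pressure(f0, xs), pressure(fz, xs), tolerance = 1e-15)
  expect_equal(axial_velocity(f0, xs, 0.5), axial_velocity(fz, xs, 0.5),
               tolerance = 1e-15)
  expect_equal(flow_rate(f0, xs), flow_rate(fz, xs), tolerance = 1e-15)
})

test_that("system residuals pass on the seeded box and converge at order 2", {
  ps <- generate_parameter_fixtures(20)
  for (i in seq_len(nrow(ps))) {
    fld <- flow_field(dimensionless_groups(ps$p_i[i], ps$K[i], ps$A[i],
                                           ps$lambda1[i], ps$lambda2[i]))
    rep <- system_residuals(fld, nx = 20, ny = 20)
    expect_true(all(rep$pass), label = sprintf("parameter set %d", i))
  }
  # halving the step shrinks the truncation-dominated residuals ~4x
  fld <- flow_field(channel_groups())
  coarse <- system_residuals(fld, nx = 12, ny = 12, step = 2e-3,
                             tol = 1e-2)
  fine <- system_residuals(fld, nx = 12, ny = 12, step = 1e-3, tol = 1e-2)
  for (eq in c("momentum_order0", "continuity_order0")) {
    ratio <- coarse$max_residual[coarse$equation == eq] /
      fine$max_residual[fine$equation == eq]
    expect_gt(ratio, 3.2)
    expect_lt(ratio, 4.8)
  }
})

test_that("as-printed coefficients fail exactly the first-order inlet checks", {
  fld <- flow_field(channel_groups(), c3_mode = "as_printed")
  rep <- system_residuals(fld, nx = 12, ny = 12)
  bad <- rep$equation[!rep$pass]
  expect_setequal(bad, c("inlet_pressure_order1", "inlet_flow_order1"))
  expect_gt(abs(field_component(fld, "p1", 0)), 0.1)
})
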