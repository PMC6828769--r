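# Independent numerical verification of the closed-form solution: ODE
# integration of the pressure equations, finite-difference residuals of the
# order-by-order thin-channel systems, and the Newtonian limit.

#' ODE oracle for the pressure components
#'
#' Integrates the pressure equations numerically, independently of the
#' closed-form amplitudes: `p0'' = xi^2 p0` with `p0(0) = p_i`,
#' `p0'(0) = -3/(2 A (1 + lambda1))`, and
#' `p1'' = xi^2 p1 + ((1 + lambda1)/5) (p0' p0'')'` with `p1(0) = 0`,
#' `p1'(0) = -(1 + lambda1) xi^4 p_i / (10 A K)`. The first-order forcing is
#' available in two variants: `"analytic"` uses the closed-form
#' `2 xi^4 (C1^2 e^{-2 xi x} + C2^2 e^{2 xi x})`, while `"state"` rebuilds it
#' from the integrated state as `xi^2 (p0'^2 + xi^2 p0^2)`, keeping the
#' oracle fully independent of the amplitudes.
#'
#' @param groups a [dimensionless_groups()] object with `K > 0`.
#' @param order 0 to integrate the zeroth-order equation only, 1 for both.
#' @param x output grid on `[0, 1]`.
#' @param rtol,atol integrator tolerances (deSolve lsoda).
#' @param forcing `"state"` (default) or `"analytic"`.
#' @return A data frame with columns `x`, `p0`, `dp0` and (for `order = 1`)
#'   `p1`, `dp1`.
#' @export
ode_oracle_pressure <- function(groups, order = 1L,
                                x = seq(0, 1, length.out = 101),
                                rtol = 1e-10, atol = 1e-12,
                                forcing = c("state", "analytic")) {
  forcing <- match.arg(forcing)
  stopifnot(inherits(groups, "dimensionless_groups"))
  K <- groups$K
  if (is.na(K) || K <= 0) stop("ODE oracle requires K > 0", call. = FALSE)
  l1 <- groups$lambda1
  A <- groups$A
  p_i <- groups$p_i
  xi <- xi_parameter(K, l1)
  C1 <- p_i / 2 + xi / (4 * A * K)
  C2 <- p_i / 2 - xi / (4 * A * K)
  y0 <- c(p0 = p_i, dp0 = -3 / (2 * A * (1 + l1)))
  if (order >= 1L) {
    y0 <- c(y0, p1 = 0, dp1 = -(1 + l1) * xi^4 * p_i / (10 * A * K))
  }
  deriv <- function(t, y, parms) {
    d <- c(y["dp0"], xi^2 * y["p0"])
    if (order >= 1L) {
      f <- if (forcing == "analytic") {
        2 * xi^4 * (C1^2 * exp(-2 * xi * t) + C2^2 * exp(2 * xi * t))
      } else {
        xi^2 * (y[["dp0"]]^2 + xi^2 * y[["p0"]]^2)
      }
      d <- c(d, y["dp1"], xi^2 * y["p1"] + (1 + l1) / 5 * f)
    }
    list(unname(d))
  }
  sol <- deSolve::ode(y = y0, times = x, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE integration failed; istate = ", attr(sol, "istate")[1],
         call. = FALSE)
  }
  out <- as.data.frame(sol)
  names(out)[1] <- "x"
  out
}

# central finite differences
.fd_x <- function(f, x, y, h) (f(x + h, y) - f(x - h, y)) / (2 * h)
.fd_y <- function(f, x, y, h) (f(x, y + h) - f(x, y - h)) / (2 * h)
.fd_yy <- function(f, x, y, h) {
  (f(x, y + h) - 2 * f(x, y) + f(x, y - h)) / h^2
}

#' Finite-difference residuals of the order-by-order systems
#'
#' Evaluates, by central finite differences on an interior grid, the
#' residuals of the momentum and continuity equations of both perturbation
#' orders together with their wall, centerline and inlet conditions, using
#' only pointwise evaluations of the closed-form fields. Every check is
#' independent of the algebra that produced the closed forms.
#'
#' The centerline symmetry condition is checked as `du/dy(x, 0) = 0`
#' (shear-free centerline), the form consistent with the dimensional
#' statement of the problem and with the solution's parabolic profile.
#' The first-order momentum balance is checked in its once-integrated-in-`y`
#' form (both sides vanish on the centerline), which keeps the check to
#' first and second differences; its third-derivative differential form
#' cannot be resolved to the tolerance in double precision.
#'
#' @param field a [flow_field()].
#' @param nx,ny interior grid resolution in `x` and `y`.
#' @param step finite-difference step.
#' @param tol pass tolerance applied to each equation's max residual
#'   (inlet integrals use `tol_quad`).
#' @param tol_quad tolerance for the inlet quadrature conditions.
#' @return A data frame (one row per equation) with columns `equation`,
#'   `max_residual`, `tol`, `pass`, plus attributes `nx`, `ny`, `step`.
#' @export
system_residuals <- function(field, nx = 50L, ny = 50L, step = 1e-4,
                             tol = 1e-6, tol_quad = 1e-10) {
  stopifnot(inherits(field, "flow_field"))
  g <- field$groups
  l1 <- g$lambda1
  K <- g$K
  # interior grid; margin of several steps so nested central stencils stay
  # strictly inside the domain despite floating-point rounding
  xs <- seq(4 * step, 1 - 4 * step, length.out = nx)
  ys <- seq(-1 + 4 * step, 1 - 4 * step, length.out = ny)
  gx <- rep(xs, times = ny)
  gy <- rep(ys, each = nx)

  fc <- function(name) function(x, y) field_component(field, name, x, y)
  u0 <- fc("u0"); v0 <- fc("v0"); u1 <- fc("u1"); v1 <- fc("v1")
  p0 <- function(x, y = 0) field_component(field, "p0", x)
  p1 <- function(x, y = 0) field_component(field, "p1", x)

  res <- list()
  add <- function(id, r, tolerance = tol) {
    res[[length(res) + 1]] <<- data.frame(
      equation = id, max_residual = max(abs(r)), tol = tolerance,
      pass = max(abs(r)) <= tolerance
    )
  }

  # zeroth-order momentum and continuity
  add("momentum_order0",
      .fd_x(p0, gx, gy, step) - .fd_yy(u0, gx, gy, step) / (1 + l1))
  add("continuity_order0",
      .fd_x(u0, gx, gy, step) + .fd_y(v0, gx, gy, step))
  # zeroth-order conditions
  add("centerline_v_order0", v0(xs, 0))
  add("centerline_shear_order0", .fd_y(u0, xs, 0, step))
  add("wall_darcy_order0", v0(xs, 1) - K * p0(xs))
  add("wall_noslip_order0", u0(xs, 1))
  add("inlet_pressure_order0", p0(0) - g$p_i, tol_quad)
  qi0 <- stats::integrate(function(y) u0(0, y), 0, 1,
                          rel.tol = 1e-12, abs.tol = 1e-13)$value
  add("inlet_flow_order0", 2 * g$A * qi0 - 1, tol_quad)

  if (field$order >= 1L) {
    # first-order momentum: dp1/dx = (1/(1+l1)) d/dy[du1/dy + D0(du0/dy)].
    # Checked in its once-integrated-in-y form (both sides vanish on the
    # centerline), which needs only first and second differences of the
    # fields; differentiating a finite-difference estimate again would bury
    # the residual in rounding noise.
    brack <- function(x, y) {
      .fd_y(u1, x, y, step) +
        u0(x, y) * .fd_x(function(a, b) .fd_y(u0, a, b, step), x, y, step) +
        v0(x, y) * .fd_yy(u0, x, y, step)
    }
    add("momentum_order1_integrated",
        .fd_x(p1, gx, gy, step) * gy - brack(gx, gy) / (1 + l1))
    add("continuity_order1",
        .fd_x(u1, gx, gy, step) + .fd_y(v1, gx, gy, step))
    add("centerline_v_order1", v1(xs, 0))
    add("centerline_shear_order1", .fd_y(u1, xs, 0, step))
    add("wall_darcy_order1", v1(xs, 1) - K * p1(xs))
    add("wall_noslip_order1", u1(xs, 1))
    add("inlet_pressure_order1", p1(0), tol_quad)
    qi1 <- stats::integrate(function(y) u1(0, y), 0, 1,
                            rel.tol = 1e-12, abs.tol = 1e-13)$value
    add("inlet_flow_order1", qi1, tol_quad)
  }
  out <- do.call(rbind, res)
  attr(out, "nx") <- nx; attr(out, "ny") <- ny; attr(out, "step") <- step
  out
}

#' Newtonian-limit check
#'
#' Sets `lambda1 = lambda2 = 0` (keeping `K`, `p_i`, `A`) and verifies that
#' the solution collapses to the classical Newtonian permeable-channel flow:
#' `xi = sqrt(3K)`, an exactly parabolic axial profile
#' `u(x, y)/u(x, 0) = 1 - y^2`, and a vanishing first-order contribution.
#'
#' @param groups a [dimensionless_groups()] object (its `lambda1`,
#'   `lambda2` are overridden with 0).
#' @param x,y evaluation grid for the profile checks.
#' @return A list with elements `xi_ok`, `parabolic_max_dev`,
#'   `first_order_max`, `pass`.
#' @export
newtonian_limit_check <- function(groups, x = seq(0.05, 0.95, by = 0.1),
                                  y = seq(-0.9, 0.9, by = 0.1)) {
  stopifnot(inherits(groups, "dimensionless_groups"))
  gN <- dimensionless_groups(p_i = groups$p_i, K = groups$K, A = groups$A,
                             lambda1 = 0, lambda2 = 0, delta = groups$delta)
  f1 <- flow_field(gN, order = 1L)
  f0 <- flow_field(gN, order = 0L)
  xi_ok <- isTRUE(all.equal(gN$xi, sqrt(3 * gN$K), tolerance = 1e-14))
  gx <- rep(x, times = length(y))
  gy <- rep(y, each = length(x))
  uc <- axial_velocity(f1, gx, 0)
  dev <- abs(axial_velocity(f1, gx, gy) / uc - (1 - gy^2))
  first <- max(
    abs(axial_velocity(f1, gx, gy) - axial_velocity(f0, gx, gy)),
    abs(normal_velocity(f1, gx, gy) - normal_velocity(f0, gx, gy)),
    abs(pressure(f1, gx) - pressure(f0, gx))
  )
  list(
    xi_ok = xi_ok,
    parabolic_max_dev = max(dev),
    first_order_max = first,
    pass = xi_ok && max(dev) < 1e-12 && first == 0
  )
}
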