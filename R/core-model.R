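# Closed-form perturbation solution for creeping Jeffrey-fluid flow in a
# narrow channel with Darcy wall leakage.
#
# The solution is an expansion in the dimensionless retardation parameter
# lambda2, truncated after the first-order term. The zeroth-order pressure
# satisfies p0'' = xi^2 p0 with xi = sqrt(3K/(1+lambda1)); the first-order
# pressure satisfies p1'' = xi^2 p1 + ((1+lambda1)/5) (p0' p0'')'. Both are
# exponential sums, so every field and derivative below is evaluated exactly
# (no numerical differentiation on the solution path).

#' Decay-rate parameter of the pressure equation
#'
#' The zeroth-order pressure decays/grows like `exp(-xi*x)`/`exp(xi*x)` with
#' `xi = sqrt(3*K/(1 + lambda1))`.
#'
#' @param K dimensionless wall filtration parameter (>= 0).
#' @param lambda1 relaxation-to-retardation ratio (>= 0).
#' @return `sqrt(3*K/(1 + lambda1))` (vectorized).
#' @export
xi_parameter <- function(K, lambda1) {
  if (any(K < 0)) stop("K must be >= 0", call. = FALSE)
  if (any(lambda1 < 0)) stop("lambda1 must be >= 0", call. = FALSE)
  sqrt(3 * K / (1 + lambda1))
}

# Threshold below which K is treated as the impermeable-wall limit. C1 and C2
# individually diverge as K -> 0 while the solution does not; the limit branch
# uses the linear (Poiseuille-type) pressure instead of naive evaluation.
.K_LIMIT <- 1e-12

#' Perturbation coefficients of the pressure solution
#'
#' Computes the amplitudes of the exponential pressure modes: `C1`, `C2` for
#' the zeroth order and `C3`, `C4` for the first-order homogeneous part, plus
#' the particular-solution amplitude `alpha = (2/15) xi^2 (1 + lambda1)`.
#'
#' Two conventions for `C3` are supported. The default, `"derived"`, is the
#' value obtained from the first-order boundary conditions (zero mean inlet
#' pressure correction and zero net inlet flow correction), which makes
#' `p1(0) = 0` hold exactly. `"as_printed"` reproduces a published variant of
#' `C3` whose sign on the `(3 C1^2 - C2^2)/15` term is flipped and which
#' violates that inlet condition; it is retained for comparison only.
#'
#' @param groups a [dimensionless_groups()] object with `K > 0`.
#' @param c3_mode `"derived"` (default) or `"as_printed"`.
#' @return An object of class `perturbation_coefficients`.
#' @export
perturbation_coefficients <- function(groups,
                                      c3_mode = c("derived", "as_printed")) {
  c3_mode <- match.arg(c3_mode)
  stopifnot(inherits(groups, "dimensionless_groups"))
  K <- groups$K
  if (is.na(K) || K < .K_LIMIT) {
    stop("K is (numerically) zero: the exponential coefficients are singular; ",
         "use flow_field(), which switches to the impermeable-limit branch",
         call. = FALSE)
  }
  p_i <- groups$p_i
  A <- groups$A
  l1 <- groups$lambda1
  xi <- xi_parameter(K, l1)
  C1 <- p_i / 2 + xi / (4 * A * K)
  C2 <- p_i / 2 - xi / (4 * A * K)
  alpha <- (2 / 15) * xi^2 * (1 + l1)
  m <- p_i * xi / (20 * A * K)
  C3 <- if (c3_mode == "derived") {
    xi^2 * (1 + l1) * (m - (1 / 15) * (3 * C1^2 - C2^2))
  } else {
    xi^2 * (1 + l1) * (m + (1 / 15) * (3 * C1^2 - C2^2))
  }
  C4 <- xi^2 * (1 + l1) * (-m + (1 / 15) * (C1^2 - 3 * C2^2))
  structure(
    list(C1 = C1, C2 = C2, C3 = C3, C4 = C4, alpha = alpha,
         xi = xi, c3_mode = c3_mode),
    class = "perturbation_coefficients"
  )
}

#' @export
print.perturbation_coefficients <- function(x, ...) {
  cat(sprintf("Perturbation coefficients (c3_mode = %s)\n", x$c3_mode))
  cat(sprintf("  C1 = %.8g, C2 = %.8g\n", x$C1, x$C2))
  cat(sprintf("  C3 = %.8g, C4 = %.8g, alpha = %.8g\n", x$C3, x$C4, x$alpha))
  invisible(x)
}

# ---- exponential-sum machinery ----------------------------------------------

# A pressure component is either an exponential sum (coef_i * exp(rate_i * x))
# or an affine function a0 + a1*x (the K -> 0 limit). Derivatives of any order
# are exact.
.expsum <- function(coef, rate) list(kind = "expsum", coef = coef, rate = rate)
.affine <- function(a0, a1) list(kind = "affine", a0 = a0, a1 = a1)

.comp_eval <- function(comp, x, deriv = 0L) {
  if (comp$kind == "affine") {
    if (deriv == 0L) return(comp$a0 + comp$a1 * x)
    if (deriv == 1L) return(rep_len(comp$a1, length(x)))
    return(rep_len(0, length(x)))
  }
  out <- numeric(length(x))
  for (i in seq_along(comp$coef)) {
    out <- out + comp$coef[i] * comp$rate[i]^deriv * exp(comp$rate[i] * x)
  }
  out
}

#' Assemble an evaluable flow field
#'
#' Bundles the dimensionless groups, the perturbation coefficients and the
#' truncation order into an object whose pressure, velocity, stress and
#' derived-quantity evaluators are exact closed forms. For `K` below 1e-12 the
#' impermeable-wall limit (linear pressure, parabolic velocity, no leakage) is
#' used, since the exponential amplitudes are a removable singularity there.
#'
#' @param groups a [dimensionless_groups()] object.
#' @param order truncation order in `lambda2`: 0 (zeroth order only) or 1.
#' @param c3_mode passed to [perturbation_coefficients()].
#' @param extrapolate if `FALSE` (default), evaluations outside
#'   `x in [0, 1]`, `y in [-1, 1]` are an error.
#' @return An object of class `flow_field`.
#' @export
flow_field <- function(groups, order = 1L, c3_mode = c("derived", "as_printed"),
                       extrapolate = FALSE) {
  c3_mode <- match.arg(c3_mode)
  stopifnot(inherits(groups, "dimensionless_groups"))
  if (is.na(groups$K)) stop("groups$K is NA; supply a value", call. = FALSE)
  if (!order %in% c(0L, 1L)) stop("order must be 0 or 1", call. = FALSE)
  l1 <- groups$lambda1
  if (groups$K < .K_LIMIT) {
    p0 <- .affine(groups$p_i, -3 / (2 * groups$A * (1 + l1)))
    p1 <- .affine(0, 0)
    g <- .affine(0, 0)
    coeffs <- NULL
  } else {
    coeffs <- perturbation_coefficients(groups, c3_mode)
    xi <- coeffs$xi
    p0 <- .expsum(c(coeffs$C1, coeffs$C2), c(-xi, xi))
    p1 <- .expsum(
      c(coeffs$C3, coeffs$C4, coeffs$alpha * coeffs$C1^2,
        coeffs$alpha * coeffs$C2^2),
      c(-xi, xi, -2 * xi, 2 * xi)
    )
    # g(x) = p0'(x) p0''(x) = xi^3 (C2^2 e^{2 xi x} - C1^2 e^{-2 xi x})
    g <- .expsum(xi^3 * c(coeffs$C2^2, -coeffs$C1^2), c(2 * xi, -2 * xi))
  }
  structure(
    list(groups = groups, coeffs = coeffs, order = as.integer(order),
         c3_mode = c3_mode, extrapolate = extrapolate,
         p0 = p0, p1 = p1, g = g,
         lambda2_eff = if (order >= 1L) groups$lambda2 else 0),
    class = "flow_field"
  )
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("Flow field (order %d in lambda2, c3_mode = %s)\n",
              x$order, x$c3_mode))
  print(x$groups)
  invisible(x)
}

.check_domain <- function(field, x, y = NULL) {
  if (!field$extrapolate) {
    if (any(!is.finite(x)) || any(x < 0 | x > 1)) {
      stop("x must lie in [0, 1] (set extrapolate = TRUE to override)",
           call. = FALSE)
    }
    if (!is.null(y) && (any(!is.finite(y)) || any(y < -1 | y > 1))) {
      stop("y must lie in [-1, 1] (set extrapolate = TRUE to override)",
           call. = FALSE)
    }
  }
  invisible(NULL)
}

# n-th derivative of the truncated pressure p0 + lambda2*p1 (or components).
.p_deriv <- function(field, x, deriv = 0L,
                     part = c("total", "p0", "p1")) {
  part <- match.arg(part)
  switch(part,
    p0 = .comp_eval(field$p0, x, deriv),
    p1 = .comp_eval(field$p1, x, deriv),
    total = .comp_eval(field$p0, x, deriv) +
      field$lambda2_eff * .comp_eval(field$p1, x, deriv)
  )
}

# ---- primary field evaluators -----------------------------------------------

#' Hydrostatic pressure
#'
#' Dimensionless pressure `p(x) = p0(x) + lambda2 * p1(x)` (independent of
#' `y` after the thin-channel truncation).
#'
#' @param field a [flow_field()].
#' @param x axial positions in `[0, 1]` (vectorized).
#' @return Pressure values.
#' @export
pressure <- function(field, x) {
  stopifnot(inherits(field, "flow_field"))
  .check_domain(field, x)
  .p_deriv(field, x, 0L)
}

#' Axial velocity
#'
#' `u(x, y)`: parabolic `(y^2 - 1)` profile driven by the pressure gradient,
#' plus the first-order `(y^4 - 1)` viscoelastic correction.
#'
#' @param field a [flow_field()].
#' @param x,y coordinates (recycled to a common length); `x` in `[0, 1]`,
#'   `y` in `[-1, 1]`.
#' @return Axial velocity values.
#' @export
axial_velocity <- function(field, x, y) {
  stopifnot(inherits(field, "flow_field"))
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  .check_domain(field, x, y)
  l1 <- field$groups$lambda1
  l2 <- field$lambda2_eff
  (1 + l1) / 2 * .p_deriv(field, x, 1L) * (y^2 - 1) -
    l2 * (1 + l1)^2 / 12 * .comp_eval(field$g, x) * (y^4 - 1)
}

#' Wall-normal velocity
#'
#' `v(x, y)`: odd in `y`, equal to `K p(x)` at the wall `y = 1` (Darcy
#' seepage) up to the truncation order.
#'
#' @inheritParams axial_velocity
#' @return Normal velocity values.
#' @export
normal_velocity <- function(field, x, y) {
  stopifnot(inherits(field, "flow_field"))
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  .check_domain(field, x, y)
  l1 <- field$groups$lambda1
  l2 <- field$lambda2_eff
  -(1 + l1) / 6 * .p_deriv(field, x, 2L) * (y^3 - 3 * y) +
    l2 * (1 + l1)^2 / 60 * .comp_eval(field$g, x, 1L) * (y^5 - 5 * y)
}

#' Individual perturbation-order field components
#'
#' Gives direct access to the zeroth- and first-order solution components
#' (`p0`, `p1`, `u0`, `u1`, `v0`, `v1`), unweighted by `lambda2`. Used by the
#' verification oracles, which check the order-by-order systems separately.
#'
#' @param field a [flow_field()].
#' @param name one of `"p0"`, `"p1"`, `"u0"`, `"u1"`, `"v0"`, `"v1"`.
#' @param x,y coordinates (recycled; `y` ignored for pressures).
#' @return Component values.
#' @export
field_component <- function(field, name, x, y = 0) {
  stopifnot(inherits(field, "flow_field"))
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  .check_domain(field, x, y)
  l1 <- field$groups$lambda1
  g0 <- function(d) .comp_eval(field$g, x, d)
  switch(name,
    p0 = .p_deriv(field, x, 0L, "p0"),
    p1 = .p_deriv(field, x, 0L, "p1"),
    u0 = (1 + l1) / 2 * .p_deriv(field, x, 1L, "p0") * (y^2 - 1),
    v0 = -(1 + l1) / 6 * .p_deriv(field, x, 2L, "p0") * (y^3 - 3 * y),
    u1 = (1 + l1) / 2 * .p_deriv(field, x, 1L, "p1") * (y^2 - 1) -
      (1 + l1)^2 / 12 * g0(0L) * (y^4 - 1),
    v1 = -(1 + l1) / 6 * .p_deriv(field, x, 2L, "p1") * (y^3 - 3 * y) +
      (1 + l1)^2 / 60 * g0(1L) * (y^5 - 5 * y),
    stop(sprintf("unknown component '%s'", name), call. = FALSE)
  )
}

# ---- stresses ---------------------------------------------------------------

#' Extra-stress tensor components
#'
#' Evaluates the four dimensionless extra-stress components of the Jeffrey
#' constitutive law with the perturbation solution substituted. The
#' retardation (convective) part is evaluated with the zeroth-order fields,
#' consistent with truncation at first order in `lambda2`; `S_xy` and `S_yx`
#' are identical by construction.
#'
#' @param field a [flow_field()].
#' @param x,y coordinates (recycled).
#' @param delta channel slenderness `a/L` (defaults to the value stored in
#'   the groups, else 0, i.e. the thin-channel leading order).
#' @return A list with numeric components `S_xx`, `S_xy`, `S_yx`, `S_yy`.
#' @export
stress_components <- function(field, x, y, delta = NULL) {
  stopifnot(inherits(field, "flow_field"))
  if (is.null(delta)) {
    delta <- if (is.na(field$groups$delta)) 0 else field$groups$delta
  }
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  .check_domain(field, x, y)
  l1 <- field$groups$lambda1
  l2 <- field$lambda2_eff
  p0d <- function(d) .p_deriv(field, x, d, "p0")
  pd <- function(d) .p_deriv(field, x, d)
  gd <- function(d) .comp_eval(field$g, x, d)

  # truncated-field gradients (exact)
  ux <- (1 + l1) / 2 * pd(2L) * (y^2 - 1) -
    l2 * (1 + l1)^2 / 12 * gd(1L) * (y^4 - 1)
  uy <- (1 + l1) * pd(1L) * y - l2 * (1 + l1)^2 / 3 * gd(0L) * y^3
  vx <- -(1 + l1) / 6 * pd(3L) * (y^3 - 3 * y) +
    l2 * (1 + l1)^2 / 60 * gd(2L) * (y^5 - 5 * y)
  vy <- -ux

  # zeroth-order fields and gradients for the retardation term
  u0 <- (1 + l1) / 2 * p0d(1L) * (y^2 - 1)
  v0 <- -(1 + l1) / 6 * p0d(2L) * (y^3 - 3 * y)
  u0x <- (1 + l1) / 2 * p0d(2L) * (y^2 - 1)
  u0y <- (1 + l1) * p0d(1L) * y
  u0xx <- (1 + l1) / 2 * p0d(3L) * (y^2 - 1)
  u0xy <- (1 + l1) * p0d(2L) * y
  u0yy <- (1 + l1) * p0d(1L)
  v0x <- -(1 + l1) / 6 * p0d(3L) * (y^3 - 3 * y)
  v0xx <- -(1 + l1) / 6 * p0d(4L) * (y^3 - 3 * y)
  v0xy <- -(1 + l1) / 6 * p0d(3L) * (3 * y^2 - 3)
  D0 <- function(fx, fy) u0 * fx + v0 * fy  # zeroth-order convective operator

  S_xy <- 1 / (1 + l1) * (
    (uy + delta^2 * vx) +
      l2 * D0(u0xy + delta^2 * v0xx, u0yy + delta^2 * v0xy)
  )
  S_xx <- 2 * delta / (1 + l1) * (ux + l2 * D0(u0xx, u0xy))
  S_yy <- 2 * delta^2 / (1 + l1) * (vy + l2 * D0(-u0xx, -u0xy))
  list(S_xx = S_xx, S_xy = S_xy, S_yx = S_xy, S_yy = S_yy)
}

#' Wall shear stress
#'
#' `tau_w(x) = -S_yx` evaluated at the wall `y = 1`, including the
#' first-order retardation correction (which cancels analytically against
#' part of the velocity-gradient term, leaving `-dp/dx`).
#'
#' @param field a [flow_field()].
#' @param x axial positions in `[0, 1]`.
#' @return Wall shear stress values.
#' @export
wall_shear <- function(field, x) {
  stopifnot(inherits(field, "flow_field"))
  .check_domain(field, x)
  l1 <- field$groups$lambda1
  l2 <- field$lambda2_eff
  uy1 <- (1 + l1) * .p_deriv(field, x, 1L) -
    l2 * (1 + l1)^2 / 3 * .comp_eval(field$g, x)
  # retardation term at the wall: u0 vanishes, v0(x,1) = K p0, u0yy = (1+l1) p0'
  conv <- l2 * field$groups$K * .p_deriv(field, x, 0L, "p0") *
    (1 + l1) * .p_deriv(field, x, 1L, "p0")
  -(uy1 + conv) / (1 + l1)
}

# ---- derived quantities -----------------------------------------------------

#' Cross-sectional volume flow rate
#'
#' `Q(x) = A * integral of u over the channel height`, in units of the inlet
#' flow (`Q(0) = 1` exactly at either truncation order).
#'
#' @param field a [flow_field()].
#' @param x axial positions in `[0, 1]`.
#' @return Flow rate values.
#' @export
flow_rate <- function(field, x) {
  stopifnot(inherits(field, "flow_field"))
  .check_domain(field, x)
  l1 <- field$groups$lambda1
  l2 <- field$lambda2_eff
  -(2 / 3) * field$groups$A * (1 + l1) *
    (.p_deriv(field, x, 1L) - l2 / 5 * (1 + l1) * .comp_eval(field$g, x))
}

#' Wall leakage flux
#'
#' Per-unit-length volume loss through both walls, `q(x) = -dQ/dx`; equal to
#' `2 A K p(x)` at the truncation order.
#'
#' @inheritParams flow_rate
#' @return Leakage flux values.
#' @export
leakage_flux <- function(field, x) {
  stopifnot(inherits(field, "flow_field"))
  .check_domain(field, x)
  l1 <- field$groups$lambda1
  l2 <- field$lambda2_eff
  (2 / 3) * field$groups$A * (1 + l1) *
    (.p_deriv(field, x, 2L) - l2 / 5 * (1 + l1) * .comp_eval(field$g, x, 1L))
}

#' Fractional reabsorption
#'
#' Fraction of the inlet flow removed through the walls over the channel
#' length: `(Q(0) - Q(1)) / Q(0)`.
#'
#' @param field a [flow_field()].
#' @return A single number in `[0, 1]` for physical (non-reversed) flows.
#' @export
fractional_reabsorption <- function(field) {
  q0 <- flow_rate(field, 0)
  if (abs(q0) < .Machine$double.eps * 10) {
    stop("Q(0) = 0: fractional reabsorption undefined", call. = FALSE)
  }
  (q0 - flow_rate(field, 1)) / q0
}

#' Mean pressure difference from the inlet
#'
#' `Delta p(x) = p(0) - p(x)` (the mean over a cross-section equals the
#' pointwise pressure, which is independent of `y`).
#'
#' @inheritParams flow_rate
#' @return Pressure-difference values.
#' @export
mean_pressure_difference <- function(field, x) {
  stopifnot(inherits(field, "flow_field"))
  .check_domain(field, x)
  .p_deriv(field, 0, 0L) - .p_deriv(field, x, 0L)
}

#' Stream function
#'
#' `psi(x, y) = integral of u from the centerline to y`, in closed form.
#' `psi(x, 1) = Q(x) / (2A)` and `psi(x, 0) = 0`.
#'
#' @inheritParams axial_velocity
#' @return Stream-function values.
#' @export
stream_function <- function(field, x, y) {
  stopifnot(inherits(field, "flow_field"))
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  .check_domain(field, x, y)
  l1 <- field$groups$lambda1
  l2 <- field$lambda2_eff
  (1 + l1) / 6 * .p_deriv(field, x, 1L) * (y^3 - 3 * y) -
    l2 * (1 + l1)^2 / 60 * .comp_eval(field$g, x) * (y^5 - 5 * y)
}

#' Implicit streamline-equation residual
#'
#' The streamlines satisfy
#' `10 dp/dx (y^3 - 3y) - lambda2 (1+lambda1) p0' p0'' (y^5 - 5y) = C5`;
#' this returns the left side minus `C5`. The left side equals
#' `60/(1+lambda1) * psi(x, y)`, so its level sets coincide with stream-
#' function contours.
#'
#' @param field a [flow_field()].
#' @param x,y coordinates (recycled).
#' @param C5 streamline level constant.
#' @return Residual values (zero on the streamline of level `C5`).
#' @export
streamline_residual <- function(field, x, y, C5) {
  60 / (1 + field$groups$lambda1) * stream_function(field, x, y) - C5
}

#' Stagnation point of the axial flow
#'
#' Finds the smallest `x` in `(0, 1)` where the cross-sectional flow rate
#' `Q(x)` vanishes; downstream of it the axial flow reverses because the
#' walls have reabsorbed all the entering fluid. Returns `NA` if `Q > 0`
#' throughout the channel.
#'
#' @param field a [flow_field()].
#' @param n_grid number of grid points used to bracket the root before
#'   refinement with [stats::uniroot()].
#' @return The stagnation location, or `NA_real_` if none exists in `(0, 1)`.
#' @export
stagnation_point <- function(field, n_grid = 256L) {
  stopifnot(inherits(field, "flow_field"))
  xs <- seq(0, 1, length.out = n_grid)
  qs <- flow_rate(field, xs)
  sgn <- sign(qs)
  flip <- which(sgn[-1] * sgn[-n_grid] < 0)
  if (length(flip) == 0) {
    zero <- which(abs(qs) < 1e-14 & xs > 0 & xs < 1)
    if (length(zero) > 0) return(xs[zero[1]])
    return(NA_real_)
  }
  i <- flip[1]
  stats::uniroot(function(x) flow_rate(field, x),
                 lower = xs[i], upper = xs[i + 1], tol = 1e-12)$root
}
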