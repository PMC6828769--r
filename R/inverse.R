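# Flat-plate hemodialyzer application: ultrafiltration rate, exit mean
# pressure drop, and the inverse estimation of the wall filtration parameter
# K (hence the membrane's mechanical filtration coefficient Lp) from a
# measured ultrafiltration rate.
#
# The ultrafiltration rate QA = Q(0) - Q(1) admits a closed form in
# cosh(xi), xi*sinh(xi), cosh(2 xi) and xi*sinh(2 xi), all of which are
# entire functions of K (xi^2 = 3K/(1+lambda1)). The inverse solve replaces
# them by Maclaurin series truncated at K^order and solves the resulting
# polynomial, mirroring how the device data are fitted in practice.

# Closed-form ultrafiltration rate QA = Q(0) - Q(1) in the entire-in-K
# building blocks cosh(xi), xi sinh(xi), cosh(2 xi), xi sinh(2 xi). This is
# the published exit expression; it agrees with the flow-rate path evaluated
# with the boundary-condition-consistent ("derived") coefficients to machine
# precision, which corroborates that the lone sign defect in the printed
# coefficient C3 did not propagate into the exit quantities.
.qa_closed_form <- function(K, p_i, A, lambda1, lambda2) {
  xi <- sqrt(3 * K / (1 + lambda1))
  C <- cosh(xi); S <- xi * sinh(xi)
  C2 <- cosh(2 * xi); S2 <- xi * sinh(2 * xi)
  1 - C + (2 / 3) * (1 + lambda1) * A * p_i * S +
    lambda2 * (
      (p_i / 5) * K * C - S / (10 * A) -
        (2 / 15) * A * (1 + lambda1) * p_i^2 * K * S -
        (p_i / 5) * K * C2 + S2 / (20 * A) +
        (1 / 15) * A * (1 + lambda1) * p_i^2 * K * S2
    )
}

.dp_exit_printed <- function(K, p_i, A, lambda1, lambda2) {
  xi <- sqrt(3 * K / (1 + lambda1))
  p_i + (xi / (10 * A * K)) * (5 - lambda2 * K * p_i) * sinh(xi) +
    (xi * p_i * lambda2 / (5 * A)) * sinh(2 * xi) +
    (1 / (20 * A^2 * (1 + lambda1))) *
      (3 * lambda2 + (4 * A^2 * K * p_i^2 * lambda2 - 20 * A^2 * p_i) *
         (1 + lambda1)) * cosh(xi) -
    (lambda2 / (20 * A^2 * (1 + lambda1))) *
      (3 + 4 * A^2 * K * p_i^2 * (1 + lambda1)) * cosh(2 * xi)
}

#' Dimensionless ultrafiltration rate
#'
#' The fluid volume lost through the permeable walls between inlet and exit,
#' as a fraction of the inlet flow: `QA = Q(0) - Q(1)`. The default path
#' evaluates the flow-rate expression of the solution with derived-mode
#' coefficients; `mode = "as_printed"` evaluates the published hyperbolic
#' closed form verbatim. The two agree to machine precision (the closed form
#' is consistent with the boundary-condition-corrected coefficients; see
#' [perturbation_coefficients()]); the `details` output keeps both so the
#' agreement is checkable.
#'
#' @param groups a [dimensionless_groups()] object.
#' @param mode `"derived"` (default) or `"as_printed"`.
#' @param details if `TRUE`, return a list with both paths.
#' @return The ultrafiltration rate, or a list
#'   `(value, derived, as_printed, discrepancy)` when `details = TRUE`.
#' @export
ultrafiltration_rate <- function(groups, mode = c("derived", "as_printed"),
                                 details = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(groups, "dimensionless_groups"))
  if (is.na(groups$K)) stop("groups$K is NA; supply a value", call. = FALSE)
  if (groups$K == 0) {
    derived <- 0
    printed <- 0
  } else {
    fld <- flow_field(groups, order = 1L, c3_mode = "derived")
    derived <- flow_rate(fld, 0) - flow_rate(fld, 1)
    printed <- .qa_closed_form(groups$K, groups$p_i, groups$A,
                               groups$lambda1, groups$lambda2)
  }
  if (details) {
    list(value = if (mode == "derived") derived else printed,
         derived = derived, as_printed = printed,
         discrepancy = derived - printed)
  } else {
    if (mode == "derived") derived else printed
  }
}

#' Mean pressure drop between inlet and exit
#'
#' `Delta p(1) = p(0) - p(1)` in dimensionless form. The default path uses
#' [mean_pressure_difference()] on the derived-mode field;
#' `mode = "as_printed"` evaluates the published exit closed form verbatim.
#'
#' @inheritParams ultrafiltration_rate
#' @return The dimensionless exit mean pressure drop, or a list with both
#'   paths when `details = TRUE`.
#' @export
mean_pressure_drop_exit <- function(groups, mode = c("derived", "as_printed"),
                                    details = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(groups, "dimensionless_groups"))
  if (is.na(groups$K)) stop("groups$K is NA; supply a value", call. = FALSE)
  fld <- flow_field(groups, order = 1L, c3_mode = "derived")
  derived <- mean_pressure_difference(fld, 1)
  printed <- if (groups$K < 1e-12) derived else
    .dp_exit_printed(groups$K, groups$p_i, groups$A,
                     groups$lambda1, groups$lambda2)
  if (details) {
    list(value = if (mode == "derived") derived else printed,
         derived = derived, as_printed = printed,
         discrepancy = derived - printed)
  } else {
    if (mode == "derived") derived else printed
  }
}

# ---- series solve for K ------------------------------------------------------

# Ascending-coefficient polynomial helpers.
.poly_add <- function(a, b) {
  n <- max(length(a), length(b))
  c(a, numeric(n - length(a))) + c(b, numeric(n - length(b)))
}
.poly_shift <- function(a) c(0, a)  # multiply by K
.poly_eval <- function(a, x) {
  out <- 0
  for (i in rev(seq_along(a))) out <- out * x + a[i]
  out
}

# Maclaurin coefficients in K (ascending, length order + 1) of the four
# entire building blocks, with c0 = 3/(1 + lambda1):
#   cosh(xi)        = sum (c0 K)^n / (2n)!
#   xi sinh(xi)     = sum (c0 K)^(n+1) / (2n+1)!
#   cosh(2 xi)      = sum (4 c0 K)^n / (2n)!
#   xi sinh(2 xi)   = sum 2^(2n+1) (c0 K)^(n+1) / (2n+1)!
.qa_polynomial <- function(p_i, A, lambda1, lambda2, order) {
  c0 <- 3 / (1 + lambda1)
  n <- 0:order
  Cp <- c0^n / factorial(2 * n)
  C2p <- (4 * c0)^n / factorial(2 * n)
  m <- 0:(order - 1)
  Sp <- c(0, c0^(m + 1) / factorial(2 * m + 1))
  S2p <- c(0, 2^(2 * m + 1) * c0^(m + 1) / factorial(2 * m + 1))

  out <- .poly_add(1, -Cp)
  out <- .poly_add(out, (2 / 3) * (1 + lambda1) * A * p_i * Sp)
  l2part <- (p_i / 5) * .poly_shift(Cp)
  l2part <- .poly_add(l2part, -Sp / (10 * A))
  l2part <- .poly_add(l2part,
                      -(2 / 15) * A * (1 + lambda1) * p_i^2 * .poly_shift(Sp))
  l2part <- .poly_add(l2part, -(p_i / 5) * .poly_shift(C2p))
  l2part <- .poly_add(l2part, S2p / (20 * A))
  l2part <- .poly_add(l2part,
                      (1 / 15) * A * (1 + lambda1) * p_i^2 * .poly_shift(S2p))
  .poly_add(out, lambda2 * l2part)
}

#' Estimate the wall filtration parameter from an ultrafiltration rate
#'
#' Solves `QA(K) = QA_target` for `K`. The hyperbolic functions in the
#' closed-form ultrafiltration expression are replaced by their Maclaurin
#' expansions in `K` truncated at `K^order` (they are entire in `K` because
#' `xi^2 = 3K/(1+lambda1)`), and the resulting polynomial is solved for all
#' roots; the smallest strictly positive real root is returned. The root of
#' the untruncated nonlinear equation, found by bracketing, is reported
#' alongside as a diagnostic.
#'
#' @param QA_target measured dimensionless ultrafiltration rate, in `(0, 1)`:
#'   per-compartment ultrafiltration flow divided by per-compartment inlet
#'   flow.
#' @param groups a [dimensionless_groups()] object supplying `p_i`, `A`,
#'   `lambda1`, `lambda2` (its `K` is ignored and may be `NA`).
#' @param order truncation order of the series in `K` (>= 2; default 3).
#' @param mode kept for interface symmetry with [ultrafiltration_rate()];
#'   the closed form being inverted is identical in both modes (see Details
#'   there), so the estimate does not depend on it.
#' @return An object of class `k_estimate`: a list with `K_est`, `K_exact`,
#'   `roots` (all polynomial roots with residuals of the exact equation),
#'   `order`, `mode`, `QA_target`.
#' @export
estimate_K <- function(QA_target, groups, order = 3L,
                       mode = c("derived", "as_printed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(groups, "dimensionless_groups"))
  if (!is.finite(QA_target) || QA_target <= 0 || QA_target >= 1) {
    stop("QA_target must lie in (0, 1)", call. = FALSE)
  }
  if (order < 2L) stop("order must be >= 2", call. = FALSE)
  p_i <- groups$p_i; A <- groups$A
  l1 <- groups$lambda1; l2 <- groups$lambda2

  poly <- .qa_polynomial(p_i, A, l1, l2, order)
  poly[1] <- poly[1] - QA_target
  roots <- polyroot(poly)
  re <- Re(roots); im <- Im(roots)
  is_real <- abs(im) <= 1e-8 * pmax(1, abs(re))
  qa_exact <- function(K) .qa_closed_form(K, p_i, A, l1, l2)
  root_tbl <- data.frame(
    Re = re, Im = im, real = is_real,
    residual = ifelse(is_real & re > 0,
                      vapply(re, function(k) {
                        if (k > 0) qa_exact(k) - QA_target else NA_real_
                      }, numeric(1)),
                      NA_real_)
  )
  pos <- sort(re[is_real & re > 0])
  if (length(pos) == 0) {
    stop(paste0("no strictly positive real root of the order-", order,
                " polynomial; roots: ",
                paste(sprintf("%.4g%+.4gi", re, im), collapse = ", ")),
         call. = FALSE)
  }
  K_est <- pos[1]

  # diagnostic: bracketed solve of the untruncated equation
  K_hi <- max(2 * K_est, 1e-6)
  f <- function(K) qa_exact(K) - QA_target
  tries <- 0
  while (f(K_hi) < 0 && tries < 60) {
    K_hi <- 2 * K_hi
    tries <- tries + 1
  }
  K_exact <- if (f(K_hi) >= 0) {
    stats::uniroot(f, lower = 0, upper = K_hi, tol = 1e-14)$root
  } else {
    NA_real_
  }
  structure(
    list(K_est = K_est, K_exact = K_exact, roots = root_tbl,
         order = as.integer(order), mode = mode, QA_target = QA_target),
    class = "k_estimate"
  )
}

#' @export
print.k_estimate <- function(x, ...) {
  cat(sprintf("K estimate from QA = %.6g (order-%d series, %s mode)\n",
              x$QA_target, x$order, x$mode))
  cat(sprintf("  K_est   = %.6g (smallest positive real root)\n", x$K_est))
  cat(sprintf("  K_exact = %.6g (untruncated equation)\n", x$K_exact))
  invisible(x)
}

# ---- permeability conversions -----------------------------------------------

#' Mechanical filtration coefficient from the dimensionless parameter
#'
#' Inverts `K = Lp L^2 / (a^3 t)`.
#'
#' @param K dimensionless wall filtration parameter.
#' @param a channel half-height (cm).
#' @param t membrane thickness (cm).
#' @param L channel length (cm).
#' @return `Lp` in cm^2.
#' @export
lp_from_K <- function(K, a, t, L) {
  if (any(a <= 0) || any(t <= 0) || any(L <= 0)) {
    stop("geometry must be strictly positive", call. = FALSE)
  }
  K * a^3 * t / L^2
}

#' Dimensionless filtration parameter from the mechanical coefficient
#'
#' @param Lp mechanical filtration coefficient (cm^2).
#' @inheritParams lp_from_K
#' @return `K = Lp L^2 / (a^3 t)` (dimensionless).
#' @export
K_from_lp <- function(Lp, a, t, L) {
  if (any(a <= 0) || any(t <= 0) || any(L <= 0)) {
    stop("geometry must be strictly positive", call. = FALSE)
  }
  Lp * L^2 / (a^3 * t)
}

#' Mechanical filtration coefficient from hydraulic permeability
#'
#' Membrane data sheets often quote the hydraulic permeability
#' `k_h = Lp / (mu t)` instead of `Lp` itself; this inverts that relation.
#'
#' @param k_h hydraulic permeability (cm^3 / dyn s).
#' @param mu fluid dynamic viscosity (dyn s / cm^2).
#' @param t membrane thickness (cm).
#' @return `Lp = k_h * mu * t` in cm^2.
#' @export
lp_from_hydraulic_permeability <- function(k_h, mu, t) {
  k_h * mu * t
}

#' Ultrafiltration rate as a function of membrane thickness
#'
#' For a fixed mechanical filtration coefficient, recomputes `K` and the
#' ultrafiltration rate at each candidate membrane thickness. In the small-K
#' regime `QA` is approximately inversely proportional to `t` (halving the
#' thickness roughly doubles the ultrafiltration rate); the `QA_t` column
#' (the product `QA * t`) makes the drift from exact inverse proportionality
#' visible.
#'
#' @param Lp mechanical filtration coefficient (cm^2).
#' @param spec a [dimensional_spec()] providing geometry, rheology and
#'   operating conditions.
#' @param t_values candidate membrane thicknesses (cm, strictly positive).
#' @return A data frame with columns `t`, `K`, `QA`, `QA_t`.
#' @export
thickness_scan <- function(Lp, spec, t_values) {
  stopifnot(inherits(spec, "dimensional_spec"))
  if (any(t_values <= 0)) stop("thicknesses must be positive", call. = FALSE)
  rows <- lapply(t_values, function(tv) {
    K <- K_from_lp(Lp, spec$a, tv, spec$L)
    g <- to_dimensionless(spec, allow_missing_permeability = TRUE)
    g$K <- K
    g$xi <- xi_parameter(K, g$lambda1)
    qa <- ultrafiltration_rate(g)
    data.frame(t = tv, K = K, QA = qa, QA_t = qa * tv)
  })
  do.call(rbind, rows)
}
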