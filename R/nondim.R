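# Nondimensionalization of the porous-walled channel problem.
#
# Dimensional quantities are held in CGS units internally (cm, s, dyn).
# Pressures may be supplied in mm Hg; the conversion constant is fixed at
# 1 mm Hg = 1333.22 dyn/cm^2.

#' Conversion constant: dyn/cm^2 per mm Hg
#'
#' @format A length-one numeric.
#' @export
MMHG_TO_DYN_CM2 <- 1333.22

# Unit conversion factors to CGS, keyed by the unit tag used in config files
# and constructors. Each entry maps a tagged value to its CGS equivalent.
.unit_factors <- list(
  # length
  cm = 1, mm = 0.1, m = 100,
  # dynamic viscosity (poise = dyn s / cm^2)
  dyn_s_cm2 = 1, P = 1, cP = 0.01,
  # pressure
  dyn_cm2 = 1, mmHg = 1333.22,
  # volume flow
  cm3_s = 1, ml_s = 1, ml_min = 1 / 60, ml_hr = 1 / 3600,
  # time
  s = 1, ms = 1e-3,
  # mechanical filtration coefficient
  cm2 = 1,
  # hydraulic permeability
  cm3_dyn_s = 1
)

.convert_unit <- function(value, unit, field) {
  f <- .unit_factors[[unit]]
  if (is.null(f)) {
    stop(sprintf("unknown unit tag '%s' for field '%s'", unit, field),
         call. = FALSE)
  }
  value * f
}

#' Dimensional specification of a porous-walled channel problem
#'
#' Collects the fluid rheology, channel and membrane geometry and operating
#' conditions of a parallel-plate channel with Darcy wall leakage, as used for
#' a single blood compartment of a flat-plate hemodialyzer. All values are in
#' CGS units (cm, s, dyn); supply pressures in dyn/cm^2 (use
#' [MMHG_TO_DYN_CM2] to convert from mm Hg).
#'
#' @param mu dynamic viscosity (dyn s/cm^2).
#' @param a channel half-height (cm).
#' @param L channel (membrane) length (cm).
#' @param w channel (membrane) width (cm).
#' @param t membrane thickness (cm).
#' @param Q_i_tilde inlet volume flow rate per channel (cm^3/s).
#' @param p_i_tilde mean inlet pressure (dyn/cm^2). When `p_m = 0` this is
#'   interpreted directly as the entrance trans-membrane pressure difference.
#' @param p_m back pressure outside the wall (hydrostatic minus osmotic,
#'   dyn/cm^2); defaults to 0.
#' @param lambda1 ratio of relaxation to retardation time (dimensionless,
#'   >= 0); 0 gives a Newtonian fluid.
#' @param lambda2_tilde retardation time (s), or `NA` if `lambda2` is given
#'   directly.
#' @param lambda2 dimensionless retardation parameter; overrides
#'   `lambda2_tilde` when supplied.
#' @param Lp mechanical filtration coefficient of the wall (cm^2); optional.
#' @param k_h hydraulic permeability (cm^3/dyn s); optional alternative to
#'   `Lp`, related by `Lp = k_h * mu * t`.
#' @param n_compartments number of blood compartments in the device.
#' @param Q_w_total total device ultrafiltration rate (cm^3/s); optional,
#'   used as the measured target of the inverse problem.
#'
#' @return An object of class `dimensional_spec`.
#' @seealso [to_dimensionless()], [read_flow_config()]
#' @export
dimensional_spec <- function(mu, a, L, w, t, Q_i_tilde, p_i_tilde,
                             p_m = 0, lambda1 = 0, lambda2_tilde = NA_real_,
                             lambda2 = NA_real_, Lp = NA_real_,
                             k_h = NA_real_, n_compartments = 1L,
                             Q_w_total = NA_real_) {
  spec <- list(
    mu = mu, a = a, L = L, w = w, t = t,
    Q_i_tilde = Q_i_tilde, p_i_tilde = p_i_tilde, p_m = p_m,
    lambda1 = lambda1, lambda2_tilde = lambda2_tilde, lambda2 = lambda2,
    Lp = Lp, k_h = k_h,
    n_compartments = as.integer(n_compartments), Q_w_total = Q_w_total
  )
  class(spec) <- "dimensional_spec"
  validate_dimensional_spec(spec)
  spec
}

#' @export
print.dimensional_spec <- function(x, ...) {
  cat("Dimensional channel specification (CGS units)\n")
  cat(sprintf("  geometry: a = %g cm, L = %g cm, w = %g cm, t = %g cm\n",
              x$a, x$L, x$w, x$t))
  cat(sprintf("  fluid:    mu = %g dyn s/cm2, lambda1 = %g\n", x$mu, x$lambda1))
  cat(sprintf("  inlet:    Q_i = %g cm3/s per channel, p_i - p_m = %g dyn/cm2 (%.3g mm Hg)\n",
              x$Q_i_tilde, x$p_i_tilde - x$p_m,
              (x$p_i_tilde - x$p_m) / MMHG_TO_DYN_CM2))
  if (!is.na(x$Lp)) cat(sprintf("  wall:     Lp = %g cm2\n", x$Lp))
  if (!is.na(x$k_h)) cat(sprintf("  wall:     k_h = %g cm3/dyn s\n", x$k_h))
  cat(sprintf("  device:   %d compartment(s)\n", x$n_compartments))
  invisible(x)
}

validate_dimensional_spec <- function(spec) {
  pos <- c("mu", "a", "L", "w", "t", "Q_i_tilde")
  for (f in pos) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("field '%s' must be a single positive finite number", f),
           call. = FALSE)
    }
  }
  if (spec$lambda1 < 0) stop("lambda1 must be >= 0", call. = FALSE)
  if (!is.na(spec$lambda2_tilde) && spec$lambda2_tilde < 0) {
    stop("lambda2_tilde must be >= 0", call. = FALSE)
  }
  if (!is.na(spec$lambda2) && spec$lambda2 < 0) {
    stop("lambda2 must be >= 0", call. = FALSE)
  }
  if (!is.na(spec$Lp) && spec$Lp < 0) stop("Lp must be >= 0", call. = FALSE)
  if (!is.na(spec$k_h) && spec$k_h < 0) stop("k_h must be >= 0", call. = FALSE)
  if (spec$n_compartments < 1L) {
    stop("n_compartments must be a positive integer", call. = FALSE)
  }
  if (spec$p_i_tilde <= spec$p_m) {
    stop("forward filtration requires p_i_tilde > p_m", call. = FALSE)
  }
  invisible(spec)
}

#' Dimensionless groups of the porous-walled channel model
#'
#' Constructs the dimensionless parameter set the perturbation solution is
#' written in: the aspect ratios `delta = a/L` and `A = w/a`, the wall
#' filtration parameter `K = Lp L^2 / (a^3 t)`, the scaled inlet pressure
#' `p_i = a^4 (p_i_tilde - p_m) / (mu L Q_i_tilde)` and the Jeffrey
#' parameters `lambda1`, `lambda2`. The derived decay rate
#' `xi = sqrt(3 K / (1 + lambda1))` is stored alongside.
#'
#' @param p_i dimensionless inlet pressure (> 0 for forward filtration).
#' @param K dimensionless wall filtration parameter (>= 0); may be `NA` for a
#'   partially specified problem whose `K` is to be estimated.
#' @param A width-to-half-height ratio (> 0).
#' @param lambda1,lambda2 Jeffrey fluid parameters (>= 0).
#' @param delta half-height-to-length ratio; optional (only the stress
#'   components depend on it).
#'
#' @return An object of class `dimensionless_groups`.
#' @export
dimensionless_groups <- function(p_i, K, A, lambda1 = 0, lambda2 = 0,
                                 delta = NA_real_) {
  if (!is.na(K) && K < 0) stop("K must be >= 0", call. = FALSE)
  if (A <= 0) stop("A must be > 0", call. = FALSE)
  if (lambda1 < 0 || lambda2 < 0) {
    stop("lambda1 and lambda2 must be >= 0", call. = FALSE)
  }
  g <- list(
    delta = delta, K = K, A = A, p_i = p_i,
    lambda1 = lambda1, lambda2 = lambda2,
    xi = if (is.na(K)) NA_real_ else xi_parameter(K, lambda1)
  )
  class(g) <- "dimensionless_groups"
  g
}

#' @export
print.dimensionless_groups <- function(x, ...) {
  cat("Dimensionless groups\n")
  cat(sprintf("  p_i = %g, K = %g, A = %g\n", x$p_i, x$K, x$A))
  cat(sprintf("  lambda1 = %g, lambda2 = %g, xi = %g\n",
              x$lambda1, x$lambda2, x$xi))
  if (!is.na(x$delta)) cat(sprintf("  delta = %g (delta^2 = %.3g)\n",
                                   x$delta, x$delta^2))
  invisible(x)
}

#' Nondimensionalize a dimensional specification
#'
#' @param spec a [dimensional_spec()].
#' @param allow_missing_permeability if `TRUE`, a spec without `Lp`/`k_h`
#'   yields groups with `K = NA` (useful when `K` is the unknown of the
#'   inverse problem); otherwise a missing permeability is an error.
#'
#' @return A [dimensionless_groups()] object.
#' @export
to_dimensionless <- function(spec, allow_missing_permeability = FALSE) {
  stopifnot(inherits(spec, "dimensional_spec"))
  validate_dimensional_spec(spec)
  Lp <- spec$Lp
  if (is.na(Lp) && !is.na(spec$k_h)) {
    Lp <- lp_from_hydraulic_permeability(spec$k_h, spec$mu, spec$t)
  }
  if (is.na(Lp)) {
    if (!allow_missing_permeability) {
      stop("spec has neither 'Lp' nor 'k_h'; supply a wall permeability or ",
           "set allow_missing_permeability = TRUE", call. = FALSE)
    }
    K <- NA_real_
  } else {
    K <- Lp * spec$L^2 / (spec$a^3 * spec$t)
  }
  lambda2 <- spec$lambda2
  if (is.na(lambda2)) {
    lambda2 <- if (is.na(spec$lambda2_tilde)) 0 else
      spec$lambda2_tilde * spec$Q_i_tilde / (spec$a^2 * spec$L)
  }
  dimensionless_groups(
    p_i = spec$a^4 * (spec$p_i_tilde - spec$p_m) /
      (spec$mu * spec$L * spec$Q_i_tilde),
    K = K,
    A = spec$w / spec$a,
    lambda1 = spec$lambda1,
    lambda2 = lambda2,
    delta = spec$a / spec$L
  )
}

#' Split a device total flow across blood compartments
#'
#' Device data sheets tabulate totals over all compartments (for instance
#' `8 Q_0` for an eight-compartment flat-plate dialyzer); the channel model
#' works per compartment. The split is deliberately explicit rather than
#' hidden inside the nondimensionalization.
#'
#' @param total_flow total device flow rate (any consistent unit).
#' @param n number of compartments (positive integer).
#' @return `total_flow / n`, in the same unit.
#' @export
per_compartment_flow <- function(total_flow, n) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  total_flow / n
}

#' Pressure scale of the dimensionless formulation
#'
#' The dimensionless pressure is `p = a^4 (p_tilde - p_m) / (mu L Q_i_tilde)`;
#' this returns the denominator-over-`a^4` factor `mu L Q_i_tilde / a^4` in
#' dyn/cm^2 per unit of dimensionless pressure.
#'
#' @param spec a [dimensional_spec()].
#' @return Pressure scale in dyn/cm^2.
#' @export
pressure_scale <- function(spec) {
  stopifnot(inherits(spec, "dimensional_spec"))
  spec$mu * spec$L * spec$Q_i_tilde / spec$a^4
}

#' Convert a dimensionless pressure back to dimensional units
#'
#' @param p dimensionless pressure (vectorized).
#' @param spec a [dimensional_spec()].
#' @return A list with components `dyn_cm2` and `mmHg`.
#' @export
pressure_to_dimensional <- function(p, spec) {
  s <- pressure_scale(spec)
  dyn <- p * s
  list(dyn_cm2 = dyn, mmHg = dyn / MMHG_TO_DYN_CM2)
}

# ---- configuration files ----------------------------------------------------

# Fields that require a unit tag, with their admissible tags.
.config_units <- list(
  mu = c("dyn_s_cm2", "P", "cP"),
  a = c("cm", "mm", "m"), L = c("cm", "mm", "m"),
  w = c("cm", "mm", "m"), t = c("cm", "mm", "m"),
  Lp = "cm2", k_h = "cm3_dyn_s",
  p_i_tilde = c("mmHg", "dyn_cm2"), p_m = c("mmHg", "dyn_cm2"),
  Q_i_tilde = c("cm3_s", "ml_s", "ml_min", "ml_hr"),
  Q_total = c("cm3_s", "ml_s", "ml_min", "ml_hr"),
  Q_w_total = c("cm3_s", "ml_s", "ml_min", "ml_hr"),
  lambda2_tilde = c("s", "ms")
)
.config_unitless <- c("lambda1", "lambda2", "n_compartments")

#' Read a flat key/value flow configuration file
#'
#' The configuration dialect is a flat YAML mapping whose keys are
#' `field.unit` pairs (for example `a.cm: 9e-3`, `p_i_tilde.mmHg: 150`,
#' `Q_total.ml_min: 160`). Units are mandatory for every dimensional field;
#' there is no silent unit guessing. Dimensionless fields (`lambda1`,
#' `lambda2`, `n_compartments`) carry no unit suffix. `Q_total` gives the
#' device total inlet flow, split explicitly over `n_compartments` by
#' [as_dimensional_spec()]; alternatively `Q_i_tilde` gives the
#' per-compartment flow directly.
#'
#' @param path path to the configuration file.
#' @return A named list of CGS values with class `flow_config`.
#' @seealso [as_dimensional_spec()], [rp_kidney_config()]
#' @export
read_flow_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw)) || any(names(raw) == "")) {
    stop("config must be a flat mapping of 'field.unit: value' entries",
         call. = FALSE)
  }
  out <- list()
  for (key in names(raw)) {
    value <- raw[[key]]
    if (is.character(value) && length(value) == 1L) {
      # YAML leaves exponent forms without a decimal point (e.g. 9e-3)
      # as strings; accept them when they parse as numbers
      coerced <- suppressWarnings(as.numeric(value))
      if (!is.na(coerced)) value <- coerced
    }
    if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
      stop(sprintf("config key '%s' must have a single numeric value", key),
           call. = FALSE)
    }
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    field <- parts[1]
    if (field %in% .config_unitless) {
      if (length(parts) != 1L) {
        stop(sprintf("field '%s' is dimensionless; drop the unit suffix", field),
             call. = FALSE)
      }
      out[[field]] <- value
    } else if (field %in% names(.config_units)) {
      if (length(parts) != 2L) {
        stop(sprintf("field '%s' requires a unit suffix, e.g. '%s.%s'",
                     field, field, .config_units[[field]][1]), call. = FALSE)
      }
      unit <- parts[2]
      if (!unit %in% .config_units[[field]]) {
        stop(sprintf("unit '%s' is not valid for field '%s' (allowed: %s)",
                     unit, field,
                     paste(.config_units[[field]], collapse = ", ")),
             call. = FALSE)
      }
      out[[field]] <- .convert_unit(value, unit, field)
    } else {
      stop(sprintf("unknown config field '%s'", field), call. = FALSE)
    }
  }
  class(out) <- "flow_config"
  out
}

#' Build a dimensional specification from a configuration
#'
#' Resolves device totals to per-compartment flows via
#' [per_compartment_flow()] and applies the convention that a configuration
#' giving the trans-membrane pressure difference directly has `p_m = 0`.
#'
#' @param config a `flow_config` from [read_flow_config()].
#' @return A [dimensional_spec()].
#' @export
as_dimensional_spec <- function(config) {
  stopifnot(inherits(config, "flow_config"))
  n <- if (is.null(config$n_compartments)) 1L else
    as.integer(config$n_compartments)
  Qi <- config$Q_i_tilde
  if (is.null(Qi)) {
    if (is.null(config$Q_total)) {
      stop("config must give either 'Q_i_tilde' or 'Q_total'", call. = FALSE)
    }
    Qi <- per_compartment_flow(config$Q_total, n)
  }
  grab <- function(name, default = NA_real_) {
    if (is.null(config[[name]])) default else config[[name]]
  }
  dimensional_spec(
    mu = config$mu, a = config$a, L = config$L, w = config$w, t = config$t,
    Q_i_tilde = Qi,
    p_i_tilde = config$p_i_tilde,
    p_m = grab("p_m", 0),
    lambda1 = grab("lambda1", 0),
    lambda2_tilde = grab("lambda2_tilde"),
    lambda2 = grab("lambda2"),
    Lp = grab("Lp"), k_h = grab("k_h"),
    n_compartments = n,
    Q_w_total = grab("Q_w_total")
  )
}

#' Path to the bundled RP-kidney configuration
#'
#' Operating data for the RP disposable flat-plate artificial kidney
#' (eight blood compartments, regenerated-cellulose membranes), as published
#' for that device, plus the Jeffrey parameters `lambda1 = 0.1`,
#' `lambda2 = 0.03` used for blood.
#'
#' @return Path to the installed `rp_kidney.yaml` file.
#' @examples
#' spec <- as_dimensional_spec(read_flow_config(rp_kidney_config()))
#' to_dimensionless(spec, allow_missing_permeability = TRUE)
#' @export
rp_kidney_config <- function() {
  system.file("extdata", "rp_kidney.yaml", package = "jeffreyflow",
              mustWork = TRUE)
}
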