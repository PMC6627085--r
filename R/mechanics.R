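# Sphere-indentation elastography for soft hydrogels.
#
# A dense sphere resting on an immersed gel indents it under its buoyant
# weight. Classical Hertz contact relates load F, sphere radius R and
# indentation depth delta to the elastic modulus E of a half-space; for a film
# of finite thickness h the half-space assumption fails and a multiplicative
# thin-film correction in the confinement parameter omega = sqrt(R*delta)/h is
# applied (frictionless gel/sphere and gel/substrate contact). All mechanics
# are SI internally (m, kg, N, Pa).

#' Spherical indenter specification
#'
#' Describes a rigid spherical indenter by its diameter and material density.
#' The applied load is the buoyant weight of the sphere, so density (not mass)
#' is the primary material property.
#'
#' @param name Identifier (free text).
#' @param diameter Sphere diameter in metres.
#' @param density Material density in kg/m^3.
#' @return An object of class `indenter_spec` with fields `name`, `diameter`,
#'   `radius` and `density`.
#' @seealso [indenter_catalog()] for the built-in bearing-ball indenters.
#' @export
indenter_spec <- function(name, diameter, density) {
  check_scalar(diameter, "diameter", positive = TRUE)
  check_scalar(density, "density", positive = TRUE)
  structure(
    list(name = as.character(name)[1], diameter = diameter,
         radius = diameter / 2, density = density),
    class = "indenter_spec"
  )
}

#' @export
print.indenter_spec <- function(x, ...) {
  cat(sprintf("<indenter_spec> %s: d = %.4g mm, rho = %.4g g/cm^3\n",
              x$name, x$diameter * 1e3, x$density / 1e3))
  invisible(x)
}

#' Built-in indenter catalog
#'
#' Bearing-ball indenters used for soft-gel indentation: 1/32 inch silicon
#' nitride (3.184 g/cm^3), 1/32 inch zirconium dioxide (5.680 g/cm^3) and
#' 1/8 inch tungsten carbide (15.630 g/cm^3). Denser spheres are chosen for
#' stiffer gels so the indentation stays measurable.
#'
#' @param name Optional catalog key (`"si3n4_1_32"`, `"zro2_1_32"`,
#'   `"wc_1_8"`). When omitted the whole catalog is returned.
#' @return A single [indenter_spec()] or a named list of them.
#' @export
indenter_catalog <- function(name = NULL) {
  inch <- 0.0254
  cat_ <- list(
    si3n4_1_32 = indenter_spec("si3n4_1_32", inch / 32, 3184),
    zro2_1_32  = indenter_spec("zro2_1_32",  inch / 32, 5680),
    wc_1_8     = indenter_spec("wc_1_8",     inch / 8,  15630)
  )
  if (is.null(name)) return(cat_)
  if (!name %in% names(cat_)) {
    ntk_abort("ntk_domain_error",
              sprintf("unknown indenter '%s' (catalog: %s)", name,
                      paste(names(cat_), collapse = ", ")))
  }
  cat_[[name]]
}

#' Immersion medium specification
#'
#' The indenter rests immersed in aqueous supernatant, so its effective weight
#' is buoyancy-corrected against the medium density.
#'
#' @param density Medium density in kg/m^3 (default 1000, water).
#' @param g Gravitational acceleration in m/s^2 (default 9.81).
#' @export
medium_spec <- function(density = 1000, g = 9.81) {
  check_scalar(density, "density", positive = TRUE)
  check_scalar(g, "g", positive = TRUE)
  structure(list(density = density, g = g), class = "medium_spec")
}

#' Gel measurement (thickness and indentation depth)
#'
#' @param thickness_h Gel thickness h in metres.
#' @param indentation_delta Indentation depth delta in metres; must satisfy
#'   `0 <= delta < h`.
#' @param replicate_id Optional replicate label.
#' @export
gel_measurement <- function(thickness_h, indentation_delta,
                            replicate_id = NA_character_) {
  check_scalar(thickness_h, "thickness_h", positive = TRUE)
  check_scalar(indentation_delta, "indentation_delta", nonnegative = TRUE)
  if (indentation_delta >= thickness_h) {
    ntk_abort("ntk_domain_error",
              "indentation_delta must be smaller than thickness_h")
  }
  structure(
    list(thickness_h = thickness_h, indentation_delta = indentation_delta,
         replicate_id = as.character(replicate_id)[1]),
    class = "gel_measurement"
  )
}

#' Elasticity model configuration
#'
#' @param poisson_ratio Poisson ratio nu; defaults to 0.5 (incompressible,
#'   water-dominated gel).
#' @param coefficient_grouping How the thin-film coefficient alpha is grouped:
#'   `"printed"` (literal token order, default) or `"fraction"`
#'   (`(10.05 - 0.63 h/R) / (3.1 + h^2/R^2)`). The flattened source expression
#'   is typographically ambiguous; see the methods vignette.
#' @param denominator_floor Positivity floor for the thin-film correction
#'   denominator; at or below it a typed error is raised instead of returning
#'   a non-positive modulus.
#' @export
elasticity_config <- function(poisson_ratio = 0.5,
                              coefficient_grouping = c("printed", "fraction"),
                              denominator_floor = 1e-9) {
  check_scalar(poisson_ratio, "poisson_ratio", nonnegative = TRUE)
  if (poisson_ratio > 0.5 + 1e-12) {
    ntk_abort("ntk_domain_error", "poisson_ratio must lie in [0, 0.5]")
  }
  check_scalar(denominator_floor, "denominator_floor", positive = TRUE)
  structure(
    list(poisson_ratio = poisson_ratio,
         coefficient_grouping = match.arg(coefficient_grouping),
         denominator_floor = denominator_floor),
    class = "elasticity_config"
  )
}

#' Buoyant load of an immersed spherical indenter
#'
#' F = (4/3) pi R^3 (rho_indenter - rho_medium) g. A sphere no denser than the
#' medium floats and cannot indent.
#'
#' @param indenter An [indenter_spec()].
#' @param medium A [medium_spec()].
#' @return Applied load in newtons.
#' @export
buoyant_load <- function(indenter, medium = medium_spec()) {
  stopifnot(inherits(indenter, "indenter_spec"), inherits(medium, "medium_spec"))
  force <- (4 / 3) * pi * indenter$radius^3 *
    (indenter$density - medium$density) * medium$g
  if (force <= 0) {
    ntk_abort("ntk_floating_indenter_error",
              sprintf(paste0("indenter density (%g kg/m^3) does not exceed ",
                             "medium density (%g kg/m^3): sphere floats, ",
                             "no indentation possible"),
                      indenter$density, medium$density))
  }
  force
}

#' Hertz modulus of a half-space from sphere indentation
#'
#' E_Hertz = 3 (1 - nu^2) F / (4 R^{1/2} delta^{3/2}). The delta exponent is
#' the classical 3/2 of Hertz contact (F proportional to delta^{3/2}).
#'
#' @param force Applied load in newtons.
#' @param radius Sphere radius in metres.
#' @param delta Indentation depth in metres.
#' @param nu Poisson ratio, in `[0, 1)`.
#' @return Elastic modulus in pascals.
#' @export
hertz_modulus <- function(force, radius, delta, nu = 0.5) {
  check_scalar(force, "force", positive = TRUE)
  check_scalar(radius, "radius", positive = TRUE)
  check_scalar(delta, "delta", positive = TRUE)
  check_scalar(nu, "nu", nonnegative = TRUE)
  if (nu >= 1) ntk_abort("ntk_domain_error", "nu must be < 1")
  3 * (1 - nu^2) * force / (4 * sqrt(radius) * delta^1.5)
}

#' Thin-film confinement parameter omega
#'
#' omega = (R * delta / h^2)^{1/2}; 0 at zero indentation, grows as the
#' contact "feels" the finite gel thickness.
#'
#' @inheritParams hertz_modulus
#' @param thickness_h Gel thickness in metres.
#' @export
omega_param <- function(radius, delta, thickness_h) {
  check_scalar(radius, "radius", positive = TRUE)
  check_scalar(delta, "delta", nonnegative = TRUE)
  check_scalar(thickness_h, "thickness_h", positive = TRUE)
  sqrt(radius * delta) / thickness_h
}

#' Frictionless thin-film coefficients alpha and beta
#'
#' Coefficients of the thin-film correction for a frictionless gel/indenter
#' and gel/substrate boundary. The alpha expression is typographically
#' ambiguous in its flattened source; both readings are provided:
#' \itemize{
#'   \item `printed`: alpha = 10.05 - 0.63 (h/R) (3.1 + h^2/R^2)
#'   \item `fraction`: alpha = (10.05 - 0.63 h/R) / (3.1 + h^2/R^2)
#' }
#' beta = 4.8 - 4.23 (h^2/R^2) under both. Both variants agree in the
#' thick-sample limit omega -> 0.
#'
#' @inheritParams omega_param
#' @param grouping `"printed"` or `"fraction"`.
#' @return List with `alpha`, `beta`, `grouping`.
#' @export
film_coefficients <- function(radius, thickness_h,
                              grouping = c("printed", "fraction")) {
  check_scalar(radius, "radius", positive = TRUE)
  check_scalar(thickness_h, "thickness_h", positive = TRUE)
  grouping <- match.arg(grouping)
  hr <- thickness_h / radius
  alpha <- switch(grouping,
    printed  = 10.05 - 0.63 * hr * (3.1 + hr^2),
    fraction = (10.05 - 0.63 * hr) / (3.1 + hr^2)
  )
  beta <- 4.8 - 4.23 * hr^2
  list(alpha = alpha, beta = beta, grouping = grouping)
}

#' Thin-film-corrected elastic modulus
#'
#' E_modified = E_Hertz (1 + 2.3 omega) /
#'   (1 + 1.15 omega^{1/3} + alpha omega + beta omega^2).
#' At omega = 0 this returns E_Hertz exactly. For thick-ish films (h > R) the
#' printed coefficient grouping makes the denominator polynomial change sign
#' inside the stated validity domain; a non-positive denominator signals
#' out-of-model input and raises a typed error rather than returning a
#' negative modulus.
#'
#' @param E_hertz Half-space Hertz modulus in pascals.
#' @param omega Confinement parameter (dimensionless, >= 0).
#' @param alpha,beta Thin-film coefficients from [film_coefficients()].
#' @param floor Positivity floor for the denominator.
#' @export
modified_hertz_modulus <- function(E_hertz, omega, alpha, beta, floor = 1e-9) {
  check_scalar(E_hertz, "E_hertz", positive = TRUE)
  check_scalar(omega, "omega", nonnegative = TRUE)
  check_scalar(alpha, "alpha")
  check_scalar(beta, "beta")
  if (omega == 0) return(E_hertz)
  denom <- 1 + 1.15 * omega^(1 / 3) + alpha * omega + beta * omega^2
  if (denom <= floor) {
    ntk_abort("ntk_nonpositive_denominator_error",
              sprintf(paste0("thin-film correction denominator is %.4g at ",
                             "omega = %.4g (alpha = %.4g, beta = %.4g): ",
                             "input is outside the model"),
                      denom, omega, alpha, beta))
  }
  E_hertz * (1 + 2.3 * omega) / denom
}

# Relative slack on the validity bounds so that ratios constructed in floating
# point (e.g. R = 0.3 * h) are accepted exactly at the boundary.
.validity_tol <- 1e-9

#' Check the thin-film model validity domain
#'
#' The correction is calibrated for `0.3 <= R/h <= 12.7` and
#' `delta/h <= min(0.6, R/h)` (inclusive bounds). This check is pure and
#' total: it never raises, and reports each constraint separately.
#'
#' @inheritParams omega_param
#' @return List of class `validity_report` with `R_over_h`, `delta_over_h`,
#'   per-constraint logicals `constraints`, character `violations`, and
#'   overall `valid`.
#' @export
check_validity <- function(radius, delta, thickness_h) {
  r_h <- radius / thickness_h
  d_h <- delta / thickness_h
  tol <- .validity_tol
  constraints <- c(
    "R/h >= 0.3"           = r_h >= 0.3 * (1 - tol),
    "R/h <= 12.7"          = r_h <= 12.7 * (1 + tol),
    "delta/h <= min(0.6, R/h)" = d_h <= min(0.6, r_h) * (1 + tol) + tol
  )
  constraints[is.na(constraints)] <- FALSE
  structure(
    list(R_over_h = r_h, delta_over_h = d_h, constraints = constraints,
         violations = names(constraints)[!constraints],
         valid = all(constraints)),
    class = "validity_report"
  )
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("<validity_report> R/h = %.4g, delta/h = %.4g -> %s\n",
              x$R_over_h, x$delta_over_h,
              if (x$valid) "valid" else
                paste("INVALID:", paste(x$violations, collapse = "; "))))
  invisible(x)
}

#' Elastic modulus from a single indentation measurement
#'
#' Composes the full pipeline: buoyant load, Hertz modulus, confinement
#' parameter, thin-film coefficients, corrected modulus, and the validity
#' check. All intermediates are carried in the result for audit. Validity
#' violations are reported via the `valid` flag, not raised; genuine domain
#' errors (zero indentation, non-positive thin-film denominator) propagate.
#'
#' @param indenter An [indenter_spec()].
#' @param medium A [medium_spec()].
#' @param meas A [gel_measurement()].
#' @param config An [elasticity_config()].
#' @return An object of class `modulus_result`.
#' @export
modulus_from_measurement <- function(indenter, medium = medium_spec(), meas,
                                     config = elasticity_config()) {
  stopifnot(inherits(meas, "gel_measurement"),
            inherits(config, "elasticity_config"))
  force <- buoyant_load(indenter, medium)
  R <- indenter$radius
  h <- meas$thickness_h
  delta <- meas$indentation_delta
  E_h <- hertz_modulus(force, R, delta, config$poisson_ratio)
  w <- omega_param(R, delta, h)
  co <- film_coefficients(R, h, config$coefficient_grouping)
  E_m <- modified_hertz_modulus(E_h, w, co$alpha, co$beta,
                                config$denominator_floor)
  vr <- check_validity(R, delta, h)
  structure(
    list(E_hertz = E_h, E_modified = E_m, force = force, omega = w,
         alpha = co$alpha, beta = co$beta, R_over_h = vr$R_over_h,
         delta_over_h = vr$delta_over_h, valid = vr$valid,
         violations = vr$violations, indenter = indenter$name,
         replicate_id = meas$replicate_id, nu = config$poisson_ratio,
         grouping = config$coefficient_grouping),
    class = "modulus_result"
  )
}

#' @export
print.modulus_result <- function(x, ...) {
  cat(sprintf(
    "<modulus_result> E_Hertz = %.4g Pa, E_modified = %.4g Pa (omega = %.4g)\n",
    x$E_hertz, x$E_modified, x$omega))
  cat(sprintf("  R/h = %.4g, delta/h = %.4g, %s\n", x$R_over_h, x$delta_over_h,
              if (x$valid) "valid" else
                paste("INVALID:", paste(x$violations, collapse = "; "))))
  invisible(x)
}

#' Usable indentation-depth domain of the forward model
#'
#' Scans the forward model over a log grid of indentation depths within the
#' validity bracket `(0, h * min(0.6, R/h)]` and returns the maximal prefix on
#' which the thin-film denominator stays above the floor and the modulus is
#' strictly decreasing in depth. Used by the inverse solver and the scene
#' generator.
#'
#' @inheritParams modulus_from_measurement
#' @param thickness_h Gel thickness in metres.
#' @param n_grid Grid resolution.
#' @return List with vectors `delta` and `E` (decreasing), and scalars
#'   `delta_min`, `delta_max`, `E_min`, `E_max`.
#' @export
indentation_domain <- function(indenter, medium = medium_spec(), thickness_h,
                               config = elasticity_config(), n_grid = 200L) {
  check_scalar(thickness_h, "thickness_h", positive = TRUE)
  R <- indenter$radius
  d_hi <- thickness_h * min(0.6, R / thickness_h)
  grid <- exp(seq(log(1e-12), log(d_hi), length.out = n_grid))
  E <- vapply(grid, function(d) {
    tryCatch(
      modulus_from_measurement(
        indenter, medium, gel_measurement(thickness_h, d), config)$E_modified,
      ntk_error = function(e) NA_real_)
  }, numeric(1))
  ok <- !is.na(E)
  # maximal usable prefix: finite and strictly decreasing
  keep <- which(cumsum(!ok) == 0)
  if (length(keep) >= 2L) {
    inc <- which(diff(E[keep]) >= 0)
    if (length(inc)) keep <- keep[seq_len(inc[1])]
  }
  if (length(keep) < 2L) {
    ntk_abort("ntk_no_root_error",
              "forward model has no usable monotone region for these inputs")
  }
  list(delta = grid[keep], E = E[keep],
       delta_min = grid[keep[1]], delta_max = grid[keep[length(keep)]],
       E_min = E[keep[length(keep)]], E_max = E[keep[1]])
}

#' Invert the indentation model for depth
#'
#' Finds the indentation depth delta at which the forward thin-film model
#' reproduces a target modulus, by bracketing on the monotone region from
#' [indentation_domain()] followed by root polishing in log-depth. Needed by
#' the synthetic scene generator and round-trip tests.
#'
#' @param E_target Target modulus in pascals.
#' @inheritParams indentation_domain
#' @param rel_tol Relative tolerance on the recovered modulus.
#' @return Indentation depth in metres.
#' @export
invert_indentation <- function(E_target, indenter, medium = medium_spec(),
                               thickness_h, config = elasticity_config(),
                               rel_tol = 1e-9) {
  check_scalar(E_target, "E_target", positive = TRUE)
  dom <- indentation_domain(indenter, medium, thickness_h, config)
  if (E_target > dom$E_max || E_target < dom$E_min) {
    ntk_abort("ntk_no_root_error",
              sprintf(paste0("E_target = %.4g Pa is outside the reachable ",
                             "range [%.4g, %.4g] Pa within the validity ",
                             "domain"), E_target, dom$E_min, dom$E_max))
  }
  f <- function(ld) {
    d <- exp(ld)
    log(modulus_from_measurement(
      indenter, medium, gel_measurement(thickness_h, d), config)$E_modified) -
      log(E_target)
  }
  i <- findInterval(-E_target, -dom$E)  # E decreasing -> search on negated
  lo <- dom$delta[max(i, 1L)]
  hi <- dom$delta[min(i + 1L, length(dom$delta))]
  if (lo == hi) return(lo)
  root <- stats::uniroot(f, lower = log(lo), upper = log(hi),
                         tol = 1e-15, extendInt = "no")
  delta <- exp(root$root)
  E_back <- modulus_from_measurement(
    indenter, medium, gel_measurement(thickness_h, delta), config)$E_modified
  if (abs(E_back - E_target) / E_target > rel_tol) {
    ntk_abort("ntk_no_root_error",
              sprintf("root polishing failed: residual %.3g relative",
                      abs(E_back - E_target) / E_target))
  }
  delta
}

#' Summarize replicate modulus results
#'
#' Mean, sample standard deviation (n - 1 denominator), standard error and n
#' for both the Hertz and thin-film-corrected moduli of a replicate set
#' (indentation experiments are typically run in triplicate). SD is the
#' headline dispersion; SEM is also emitted.
#'
#' @param results List of `modulus_result` objects.
#' @return A data.frame with one row per metric (`E_modified`, `E_hertz`).
#' @export
summarize_replicates <- function(results) {
  if (length(results) == 0L) {
    ntk_abort("ntk_domain_error", "no replicate results supplied")
  }
  stopifnot(all(vapply(results, inherits, logical(1), "modulus_result")))
  n <- length(results)
  if (n == 1L) {
    ntk_warn("ntk_single_replicate_warning",
             "single replicate: SD and SEM are undefined (NA)")
  }
  one <- function(field) {
    x <- vapply(results, `[[`, numeric(1), field)
    s <- if (n > 1L) stats::sd(x) else NA_real_
    data.frame(metric = field, mean = mean(x), sd = s, sem = s / sqrt(n),
               n = n, stringsAsFactors = FALSE)
  }
  rbind(one("E_modified"), one("E_hertz"))
}
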