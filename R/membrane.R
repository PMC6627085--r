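# Voltage-sensitive-dye plate-reader analytics. Raw well fluorescence (25
# area-scan reads per well in a 5x5 grid) is normalized against dye-only
# background wells, converted to a membrane-potential change via a
# Nernst/Goldman-Hodgkin-Katz-derived relation
#   deltaE = (R T / (z' F)) ln(1 / (dF/F0 + 1)),
# with the dye-sensitivity exponent z' calibrated from a KCl titration. Per-
# well coefficient of variation is the QC statistic; group comparisons use
# one-sided pooled-variance or paired t tests.

#' Electrophysiology constants
#'
#' @param temperature Absolute temperature in kelvin; default 295.15 K
#'   (22 degrees C), at which the thermal voltage RT/F is 25.43 mV.
#' @param z_prime Apparent charge of the external dye (dye-sensitivity
#'   exponent); default -0.64, within the -0.62 to -0.72 range reported for
#'   neuronal cultures. Must be nonzero.
#' @return Object of class `ephys_constants` with `gas_constant` (8.314
#'   J/mol/K), `faraday` (96485 C/mol), `temperature`, `z_prime` and the
#'   derived `thermal_voltage_mV`.
#' @export
ephys_constants <- function(temperature = 295.15, z_prime = -0.64) {
  check_scalar(temperature, "temperature", positive = TRUE)
  check_scalar(z_prime, "z_prime")
  if (z_prime == 0) ntk_abort("ntk_domain_error", "z_prime must be nonzero")
  R <- 8.314
  Fd <- 96485
  structure(
    list(gas_constant = R, faraday = Fd, temperature = temperature,
         z_prime = z_prime,
         thermal_voltage_mV = 1000 * R * temperature / Fd),
    class = "ephys_constants"
  )
}

#' One well of a plate read
#'
#' @param reads Raw fluorescence values; sample wells carry exactly 25 reads
#'   (5x5 area scan, row-major).
#' @param role `"sample"` or `"dye_only_background"`.
#' @param group Group label (e.g. `"motor_neuron"`, `"precursor"`).
#' @param condition `"rest"` or `"stimulated"`.
#' @param density Seeding density in cells/well (optional).
#' @export
well_read <- function(reads, role = c("sample", "dye_only_background"),
                      group = NA_character_,
                      condition = c("rest", "stimulated"),
                      density = NA_real_) {
  role <- match.arg(role)
  condition <- match.arg(condition)
  reads <- as.numeric(reads)
  if (any(!is.finite(reads)) || any(reads < 0)) {
    ntk_abort("ntk_domain_error", "reads must be finite and >= 0")
  }
  if (role == "sample" && length(reads) != 25L) {
    ntk_abort("ntk_domain_error",
              sprintf("sample well must have exactly 25 reads (got %d)",
                      length(reads)))
  }
  structure(
    list(reads = reads, role = role, group = as.character(group)[1],
         condition = condition, density = density),
    class = "well_read"
  )
}

#' A full plate read
#'
#' @param wells Named list of [well_read()] objects; names are well IDs
#'   (A1-H12 convention). At least one dye-only background well is required.
#' @param plate_id Plate identifier.
#' @export
plate_read <- function(wells, plate_id = "plate1") {
  stopifnot(is.list(wells), length(wells) > 0L, !is.null(names(wells)))
  stopifnot(all(vapply(wells, inherits, logical(1), "well_read")))
  roles <- vapply(wells, `[[`, character(1), "role")
  if (!any(roles == "dye_only_background")) {
    ntk_abort("ntk_missing_background_error",
              "plate has no dye-only background wells")
  }
  structure(list(plate_id = as.character(plate_id)[1], wells = wells),
            class = "plate_read")
}

#' @export
print.plate_read <- function(x, ...) {
  roles <- vapply(x$wells, `[[`, character(1), "role")
  cat(sprintf("<plate_read> %s: %d wells (%d sample, %d background)\n",
              x$plate_id, length(x$wells), sum(roles == "sample"),
              sum(roles == "dye_only_background")))
  invisible(x)
}

#' Background fluorescence F0
#'
#' Pooled mean of all reads across all dye-only background wells.
#'
#' @param plate A [plate_read()].
#' @export
background_f0 <- function(plate) {
  stopifnot(inherits(plate, "plate_read"))
  roles <- vapply(plate$wells, `[[`, character(1), "role")
  bg <- plate$wells[roles == "dye_only_background"]
  if (length(bg) == 0L) {
    ntk_abort("ntk_missing_background_error", "no background wells on plate")
  }
  mean(unlist(lapply(bg, `[[`, "reads")))
}

#' Normalized fluorescence change
#'
#' Element-wise (F - F0) / F0.
#'
#' @param reads Raw fluorescence values.
#' @param f0 Background fluorescence (> 0).
#' @export
normalize_well <- function(reads, f0) {
  if (!is.numeric(f0) || length(f0) != 1L || is.na(f0) || f0 <= 0) {
    ntk_abort("ntk_nonpositive_background_error",
              "background F0 must be a positive scalar")
  }
  (reads - f0) / f0
}

#' Membrane-potential change from normalized fluorescence
#'
#' deltaE = (R T / (z' F)) ln(1 / (dff0 + 1)), in millivolts. With z' < 0 a
#' fluorescence increase (dff0 > 0) maps to a positive deltaE
#' (depolarization). Vectorised over `dff0`.
#'
#' @param dff0 Normalized fluorescence change(s), each > -1.
#' @param constants An [ephys_constants()].
#' @return deltaE in mV.
#' @export
delta_e <- function(dff0, constants = ephys_constants()) {
  stopifnot(inherits(constants, "ephys_constants"))
  if (any(!is.finite(dff0)) || any(dff0 <= -1)) {
    ntk_abort("ntk_log_domain_error",
              "every dff0 must be finite and > -1 (log-domain requirement)")
  }
  (constants$thermal_voltage_mV / constants$z_prime) * log(1 / (dff0 + 1))
}

#' Inverse of [delta_e()]
#'
#' dff0 = exp(-z' F deltaE / (R T)) - 1. This is also the generative map used
#' by the plate simulator.
#'
#' @param delta_e_mV Membrane-potential change(s) in mV.
#' @inheritParams delta_e
#' @export
inverse_delta_e <- function(delta_e_mV, constants = ephys_constants()) {
  stopifnot(inherits(constants, "ephys_constants"))
  exp(-delta_e_mV * constants$z_prime / constants$thermal_voltage_mV) - 1
}

#' Within-well coefficient of variation
#'
#' 100 * sample SD / mean over the reads of one well. Computed on raw reads by
#' default (scale-invariant; the normalized dff0 can cross zero and break the
#' ratio). QC thresholds of 5% and 10% are flagged by [analyze_plate()].
#'
#' @param values At least two reads with nonzero mean.
#' @return COV in percent.
#' @export
well_cov <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    ntk_abort("ntk_domain_error", "COV needs at least 2 values")
  }
  m <- mean(values)
  if (m == 0) ntk_abort("ntk_zero_mean_error", "COV undefined for zero mean")
  100 * stats::sd(values) / m
}

#' KCl titration series for dye calibration
#'
#' @param points Data frame with columns `kx` (external K+ concentration, mM)
#'   and `dff0` (normalized fluorescence change per cell, each > -1);
#'   optionally `cell`.
#' @param kr Reference K+ concentration in mM (default 5.4).
#' @export
titration_series <- function(points, kr = 5.4) {
  check_scalar(kr, "kr", positive = TRUE)
  stopifnot(is.data.frame(points), all(c("kx", "dff0") %in% names(points)))
  if (any(points$kx <= 0)) {
    ntk_abort("ntk_domain_error", "all kx must be > 0")
  }
  if (any(points$dff0 <= -1)) {
    ntk_abort("ntk_log_domain_error", "all dff0 must be > -1")
  }
  structure(list(points = as.data.frame(points), kr = kr),
            class = "titration_series")
}

#' Calibrate the dye-sensitivity exponent z'
#'
#' The calibration relation is 1/(dff0 + 1) = (Kx/Kr)^{z'}. The default
#' log-log fit regresses ln(1/(dff0+1)) on ln(Kx/Kr) by ordinary least
#' squares, whose slope is z' (exactly consistent with the Nernst-derived
#' conversion). The `linear` variant regresses 1/(dff0+1) on Kx/Kr directly.
#'
#' @param series A [titration_series()] with at least 3 distinct Kx values.
#' @param fit_space `"loglog"` (default) or `"linear"`.
#' @return Object of class `z_prime_fit`: `z_prime` (slope), `intercept`,
#'   `r_squared`, `fit_space`, `n`, `residuals`.
#' @export
calibrate_z_prime <- function(series, fit_space = c("loglog", "linear")) {
  stopifnot(inherits(series, "titration_series"))
  fit_space <- match.arg(fit_space)
  pts <- series$points
  if (length(unique(pts$kx)) < 3L) {
    ntk_abort("ntk_insufficient_points_error",
              "calibration needs >= 3 distinct Kx concentrations")
  }
  ratio <- 1 / (pts$dff0 + 1)
  x <- pts$kx / series$kr
  if (fit_space == "loglog") {
    if (any(ratio <= 0)) {
      ntk_abort("ntk_log_domain_error",
                "nonpositive 1/(dff0+1) ratio in log-log space")
    }
    fit <- stats::lm(log(ratio) ~ log(x))
  } else {
    fit <- stats::lm(ratio ~ x)
  }
  co <- stats::coef(fit)
  y <- fit$model[[1]]
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(
    list(z_prime = unname(co[2]), intercept = unname(co[1]),
         r_squared = r2, fit_space = fit_space,
         n = nrow(pts), residuals = unname(stats::residuals(fit))),
    class = "z_prime_fit"
  )
}

#' @export
print.z_prime_fit <- function(x, ...) {
  cat(sprintf("<z_prime_fit> z' = %.4f (%s fit, n = %d, R^2 = %.4f)\n",
              x$z_prime, x$fit_space, x$n, x$r_squared))
  invisible(x)
}

#' One-sided t test between two groups of well means
#'
#' Hand-coded pooled-variance two-sample t (df = n1 + n2 - 2) or paired t
#' (df = n - 1), with a one-sided p-value by default ("one-way" testing:
#' equal-variance unpaired for maturity comparisons, paired for stimulated vs
#' rest). A paired comparison with zero within-pair variance and a nonzero
#' shift is degenerate and reported as an infinite t with a warning.
#'
#' @param a,b Numeric vectors of per-well mean deltaE (mV); equal length when
#'   `paired`.
#' @param paired Logical.
#' @param alternative `"greater"` (mean(a) > mean(b), default), `"less"`, or
#'   `"two.sided"`.
#' @return Object of class `group_comparison` with means, dispersions, `t`,
#'   `df`, `p_value`.
#' @export
compare_groups <- function(a, b, paired = FALSE,
                           alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    ntk_abort("ntk_domain_error", "each group needs n >= 2")
  }
  if (paired && length(a) != length(b)) {
    ntk_abort("ntk_domain_error", "paired comparison requires equal lengths")
  }
  if (paired) {
    d <- a - b
    n <- length(d)
    df <- n - 1
    sd_d <- stats::sd(d)
    if (sd_d == 0) {
      ntk_warn("ntk_degenerate_test_warning",
               "zero within-pair variance: t is infinite (or NaN at zero shift)")
      tstat <- if (mean(d) == 0) NaN else sign(mean(d)) * Inf
    } else {
      tstat <- mean(d) / (sd_d / sqrt(n))
    }
  } else {
    n1 <- length(a); n2 <- length(b)
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    if (se == 0) {
      ntk_warn("ntk_degenerate_test_warning",
               "zero pooled variance: t is infinite (or NaN at zero shift)")
      tstat <- if (mean(a) == mean(b)) NaN else sign(mean(a) - mean(b)) * Inf
    } else {
      tstat <- (mean(a) - mean(b)) / se
    }
  }
  p <- switch(alternative,
    greater   = stats::pt(tstat, df, lower.tail = FALSE),
    less      = stats::pt(tstat, df, lower.tail = TRUE),
    two.sided = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  )
  structure(
    list(mean_a = mean(a), mean_b = mean(b), sd_a = stats::sd(a),
         sd_b = stats::sd(b), n_a = length(a), n_b = length(b),
         t = tstat, df = df, p_value = unname(p), paired = paired,
         alternative = alternative),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s t = %.4g (df = %d), one-sided p = %.4g [%s]\n",
    if (x$paired) "paired" else "pooled", x$t, x$df, x$p_value,
    x$alternative))
  invisible(x)
}

#' Linearity of deltaE against seeding density
#'
#' Least-squares line and Pearson correlation of per-well mean deltaE against
#' cell density; in a homogeneous culture the relation should be linear if
#' the reader reports the dye reliably.
#'
#' @param density Cell densities (cells/well).
#' @param delta_e_mV Matching per-well mean deltaE (mV).
#' @return List with `r`, `slope`, `intercept`, `n`.
#' @export
density_linearity <- function(density, delta_e_mV) {
  if (length(unique(density)) < 3L) {
    ntk_abort("ntk_insufficient_points_error",
              "density fit needs >= 3 distinct densities")
  }
  fit <- stats::lm(delta_e_mV ~ density)
  co <- stats::coef(fit)
  list(r = stats::cor(density, delta_e_mV), slope = unname(co[2]),
       intercept = unname(co[1]), n = length(density))
}

#' Plate analysis plan
#'
#' @param comparisons List of comparison specs; each a list with `label`,
#'   `field` (`"condition"` or `"group"`), `a`, `b` (level names), `paired`,
#'   `alternative`.
#' @param cov_exclude_threshold COV percent above which wells are excluded
#'   from group statistics, or `NULL` (default) to flag only.
#' @export
plate_plan <- function(comparisons = list(), cov_exclude_threshold = NULL) {
  structure(list(comparisons = comparisons,
                 cov_exclude_threshold = cov_exclude_threshold),
            class = "plate_plan")
}

#' Analyze one plate
#'
#' Computes the pooled background F0, per-well normalized fluorescence,
#' deltaE (per read and mean), raw-read COV with 5% and 10% QC flags, the
#' planned group comparisons, and (when at least three distinct densities are
#' present) the density-linearity fit. Deterministic given its inputs.
#'
#' @param plate A [plate_read()].
#' @param constants An [ephys_constants()].
#' @param plan A [plate_plan()].
#' @return Object of class `plate_report`: `f0`, `wells` (data.frame),
#'   `comparisons`, `density_fit`.
#' @export
analyze_plate <- function(plate, constants = ephys_constants(),
                          plan = plate_plan()) {
  stopifnot(inherits(plate, "plate_read"))
  f0 <- background_f0(plate)
  roles <- vapply(plate$wells, `[[`, character(1), "role")
  samples <- plate$wells[roles == "sample"]
  if (length(samples) == 0L) {
    ntk_abort("ntk_empty_group_error", "plate has no sample wells")
  }
  rows <- lapply(names(samples), function(id) {
    w <- samples[[id]]
    dff0 <- normalize_well(w$reads, f0)
    de <- delta_e(dff0, constants)
    cov <- well_cov(w$reads)
    data.frame(well = id, group = w$group, condition = w$condition,
               density = w$density, mean_dff0 = mean(dff0),
               mean_delta_e_mV = mean(de), cov_percent = cov,
               cov_gt_5 = cov > 5, cov_gt_10 = cov > 10,
               stringsAsFactors = FALSE)
  })
  wells <- do.call(rbind, rows)
  included <- wells
  thr <- plan$cov_exclude_threshold
  if (!is.null(thr)) included <- wells[wells$cov_percent <= thr, , drop = FALSE]
  comparisons <- lapply(plan$comparisons, function(cs) {
    field <- cs$field %||% "condition"
    av <- included$mean_delta_e_mV[included[[field]] == cs$a]
    bv <- included$mean_delta_e_mV[included[[field]] == cs$b]
    if (length(av) == 0L || length(bv) == 0L) {
      ntk_abort("ntk_empty_group_error",
                sprintf("comparison '%s': empty group", cs$label %||% ""))
    }
    res <- compare_groups(av, bv, paired = isTRUE(cs$paired),
                          alternative = cs$alternative %||% "greater")
    res$label <- cs$label %||% sprintf("%s vs %s", cs$a, cs$b)
    res
  })
  density_fit <- NULL
  dd <- included[!is.na(included$density), , drop = FALSE]
  if (length(unique(dd$density)) >= 3L) {
    density_fit <- density_linearity(dd$density, dd$mean_delta_e_mV)
  }
  structure(
    list(plate_id = plate$plate_id, f0 = f0, wells = wells,
         comparisons = comparisons, density_fit = density_fit,
         constants = constants),
    class = "plate_report"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.plate_report <- function(x, ...) {
  cat(sprintf("<plate_report> %s: F0 = %.4g, %d sample wells (%d with COV > 10%%)\n",
              x$plate_id, x$f0, nrow(x$wells), sum(x$wells$cov_gt_10)))
  for (cmp in x$comparisons) {
    cat(sprintf("  %s: t = %.3g, df = %d, p = %.3g\n",
                cmp$label, cmp$t, cmp$df, cmp$p_value))
  }
  if (!is.null(x$density_fit)) {
    cat(sprintf("  density linearity: r = %.3f\n", x$density_fit$r))
  }
  invisible(x)
}
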