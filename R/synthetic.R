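# Ground-truth-known generators for every pipeline stage: indentation scenes
# (two-channel z-stacks), plate reads, and KCl titrations. Each generator is
# deterministic given (parameters, seed). Noise is multiplicative Gaussian on
# intensities (photon-scaling regime at typical plate-reader/PMT gains).

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Bead-layer surface elevation (um) for a spherical-cap depression of depth
# delta at the top of a slab: sphere of radius R_um imprinted at the field
# position (cy, cx) in um from the field centre.
cap_surface <- function(y_um, x_um, z_top, delta_um, R_um, cy = 0, cx = 0) {
  ry <- outer(y_um - cy, rep(1, length(x_um)))
  rx <- outer(rep(1, length(y_um)), x_um - cx)
  r2 <- ry^2 + rx^2
  a2 <- delta_um * (2 * R_um - delta_um)          # contact radius squared
  s <- matrix(z_top, nrow = length(y_um), ncol = length(x_um))
  inside <- r2 < a2
  if (delta_um > 0 && any(inside)) {
    s[inside] <- z_top - delta_um + (R_um - sqrt(pmax(R_um^2 - r2[inside], 0)))
  }
  s
}

# Build one two-channel stack: green slab [z0, z0 + h), red Gaussian bead
# layer centred on the (possibly depressed) surface.
build_stack <- function(z_lo, z_hi, z_step, field_px, field_um, z0, h_um,
                        delta_um, R_um, noise_cv, bead_sigma = 1.5,
                        plateau = 1000, bead_amp = 1000,
                        center_offset_um = c(0, 0)) {
  z <- seq(z_lo, z_hi, by = z_step)
  nz <- length(z)
  px <- field_um / field_px
  coords <- (seq_len(field_px) - (field_px + 1) / 2) * px
  s <- cap_surface(coords, coords, z0 + h_um, delta_um, R_um,
                   cy = center_offset_um[1], cx = center_offset_um[2])
  n_col <- field_px * field_px
  # green: slab occupancy by slice centre, uniform in (y, x) -- gel columns
  # under the indenter are still gel; the dye fills the whole slab.
  g_slice <- ifelse(z >= z0 & z < z0 + h_um, plateau, 0)
  green <- array(rep(g_slice, times = n_col), dim = c(nz, field_px, field_px))
  # red: Gaussian bead layer around the surface elevation of each column
  sv <- as.vector(s)                               # length n_col, (y,x) col-major
  red_m <- bead_amp * exp(-(outer(z, sv, `-`))^2 / (2 * bead_sigma^2))
  red <- array(red_m, dim = c(nz, field_px, field_px))
  if (noise_cv > 0) {
    green <- green * (1 + stats::rnorm(length(green), 0, noise_cv))
    red <- red * (1 + stats::rnorm(length(red), 0, noise_cv))
    green[green < 0] <- 0
    red[red < 0] <- 0
  }
  z_stack(green, red, xy_pixel_size = px, z_step = z_step, z_origin = z_lo)
}

#' Simulate a fixed-geometry indentation stack
#'
#' Low-level generator for a single two-channel stack with a directly
#' specified indentation depth (no mechanics involved): green slab of
#' thickness `h_um` starting at `z0_um`, red bead layer with a spherical-cap
#' depression of depth `delta_um` and sphere radius `R_um`.
#'
#' @param h_um Gel thickness in micrometres.
#' @param delta_um Cap depth in micrometres (0 for a flat surface).
#' @param R_um Indenting-sphere radius in micrometres.
#' @param z_step Axial step in micrometres.
#' @param field_px Field width in pixels (square field).
#' @param field_um Physical field width in micrometres; defaults to four
#'   contact radii (at least 200 um) so the periphery stays undisturbed.
#' @param z0_um Slab bottom elevation.
#' @param z_lo_um Bottom of the imaged axial range (default 0: full height).
#' @param z_margin_um Extra axial range above the slab top.
#' @param noise_cv Multiplicative Gaussian noise CV.
#' @param center_offset_um Cap centre offset (y, x) from the field centre, um.
#' @param seed RNG seed (NULL leaves the RNG state alone).
#' @return A [z_stack()].
#' @export
simulate_indent_stack <- function(h_um, delta_um, R_um, z_step = 1,
                                  field_px = 64L, field_um = NULL,
                                  z0_um = 10, z_lo_um = 0, z_margin_um = 15,
                                  noise_cv = 0, center_offset_um = c(0, 0),
                                  seed = NULL) {
  check_scalar(h_um, "h_um", positive = TRUE)
  check_scalar(delta_um, "delta_um", nonnegative = TRUE)
  check_scalar(R_um, "R_um", positive = TRUE)
  if (is.null(field_um)) {
    a <- sqrt(max(delta_um * (2 * R_um - delta_um), 0))
    field_um <- max(4 * a, 200)
  }
  with_seed(seed, build_stack(
    z_lo = z_lo_um,
    z_hi = z0_um + h_um + z_margin_um,
    z_step = z_step, field_px = field_px, field_um = field_um, z0 = z0_um,
    h_um = h_um, delta_um = delta_um, R_um = R_um, noise_cv = noise_cv,
    center_offset_um = center_offset_um))
}

#' Simulate a full indentation scene from a target modulus
#'
#' Embodies the measurement chain in reverse: the indentation depth implied by
#' `E_true` is computed with [invert_indentation()] (so the scene is exactly
#' consistent with the forward model), then rendered as two stacks: a coarse
#' full-height stack (default 5 um steps) from which thickness is measured,
#' and a fine stack of the surface region (default 1 um steps) from which the
#' depth is measured. Generated geometry is checked against the thin-film
#' validity ranges; violations refuse to generate.
#'
#' @param E_true Ground-truth elastic modulus in pascals.
#' @param indenter An [indenter_spec()]; default 1/32 inch silicon nitride.
#' @param h_um Gel thickness in micrometres (default 400, giving R/h near 1
#'   for the default indenter, where the thin-film correction is
#'   well-behaved under both coefficient groupings).
#' @param medium A [medium_spec()].
#' @param config An [elasticity_config()].
#' @param noise_cv Multiplicative intensity-noise CV (default 0.05).
#' @param coarse_z_step,fine_z_step Axial steps (um) of the thickness and
#'   surface stacks.
#' @param field_px Field width in pixels.
#' @param seed RNG seed.
#' @return List of class `indentation_scene`: `thickness_stack`,
#'   `indent_stack`, `truth` (E_true, delta_true_um, h_true_um, indenter,
#'   noise_cv, seed).
#' @export
simulate_indentation_scene <- function(E_true,
                                       indenter = indenter_catalog("si3n4_1_32"),
                                       h_um = 400, medium = medium_spec(),
                                       config = elasticity_config(),
                                       noise_cv = 0.05, coarse_z_step = 5,
                                       fine_z_step = 1, field_px = 64L,
                                       seed = NULL) {
  check_scalar(E_true, "E_true", positive = TRUE)
  h_m <- h_um * 1e-6
  delta_m <- invert_indentation(E_true, indenter, medium, h_m, config)
  delta_um <- delta_m * 1e6
  R_um <- indenter$radius * 1e6
  vr <- check_validity(indenter$radius, delta_m, h_m)
  if (!vr$valid) {
    ntk_abort("ntk_domain_error",
              sprintf("generated geometry violates validity ranges: %s",
                      paste(vr$violations, collapse = "; ")))
  }
  z0 <- 10
  a <- sqrt(delta_um * (2 * R_um - delta_um))
  field_um <- max(4 * a, 200)
  with_seed(seed, {
    thickness_stack <- build_stack(
      z_lo = 0, z_hi = z0 + h_um + 50, z_step = coarse_z_step,
      field_px = field_px, field_um = field_um, z0 = z0, h_um = h_um,
      delta_um = delta_um, R_um = R_um, noise_cv = noise_cv)
    indent_stack <- build_stack(
      z_lo = max(z0 + h_um - delta_um - 25, 0), z_hi = z0 + h_um + 15,
      z_step = fine_z_step, field_px = field_px, field_um = field_um,
      z0 = z0, h_um = h_um, delta_um = delta_um, R_um = R_um,
      noise_cv = noise_cv)
    structure(
      list(thickness_stack = thickness_stack, indent_stack = indent_stack,
           truth = list(E_true = E_true, delta_true_um = delta_um,
                        h_true_um = h_um, indenter = indenter$name,
                        noise_cv = noise_cv, seed = seed)),
      class = "indentation_scene"
    )
  })
}

#' Simulate a voltage-dye plate read
#'
#' The generative map is the exact inverse of the fluorescence-to-voltage
#' conversion: dff0 = exp(z' F deltaE / (R T)) - 1, then per-read
#' F = F0 (dff0 + 1)(1 + eps) with eps ~ Normal(0, noise_cv); 25 reads per
#' sample well plus dye-only background wells.
#'
#' @param groups Data frame with one row per well group: columns `group`,
#'   `condition` (`"rest"`/`"stimulated"`), `delta_e_mV` (true per-well mean),
#'   `n_wells`, and optionally `density`.
#' @param constants An [ephys_constants()] (the simulator's z' and T).
#' @param f0 True background fluorescence (default 200).
#' @param noise_cv Per-read multiplicative noise CV (default 0.02).
#' @param n_background Number of dye-only wells (default 3).
#' @param seed RNG seed.
#' @param plate_id Plate identifier.
#' @return A [plate_read()] with a `truth` attribute.
#' @export
simulate_plate <- function(groups, constants = ephys_constants(), f0 = 200,
                           noise_cv = 0.02, n_background = 3L, seed = NULL,
                           plate_id = "sim_plate") {
  stopifnot(is.data.frame(groups),
            all(c("group", "condition", "delta_e_mV", "n_wells") %in%
                  names(groups)))
  check_scalar(f0, "f0", positive = TRUE)
  dff0_mean <- inverse_delta_e(groups$delta_e_mV, constants)
  if (any(dff0_mean <= -1)) {
    ntk_abort("ntk_domain_error",
              "parameter combination produces dff0 <= -1; rejected")
  }
  well_ids <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))
  with_seed(seed, {
    wells <- list()
    k <- 0L
    for (i in seq_len(nrow(groups))) {
      for (j in seq_len(groups$n_wells[i])) {
        k <- k + 1L
        reads <- f0 * (dff0_mean[i] + 1) *
          (1 + stats::rnorm(25L, 0, noise_cv))
        reads[reads < 0] <- 0
        wells[[well_ids[k]]] <- well_read(
          reads, role = "sample", group = groups$group[i],
          condition = groups$condition[i],
          density = if ("density" %in% names(groups))
            groups$density[i] else NA_real_)
      }
    }
    for (j in seq_len(n_background)) {
      k <- k + 1L
      reads <- f0 * (1 + stats::rnorm(25L, 0, noise_cv))
      reads[reads < 0] <- 0
      wells[[well_ids[k]]] <- well_read(reads, role = "dye_only_background")
    }
    plate <- plate_read(wells, plate_id = plate_id)
    attr(plate, "truth") <- list(groups = groups, f0 = f0,
                                 noise_cv = noise_cv,
                                 z_prime = constants$z_prime,
                                 temperature = constants$temperature,
                                 seed = seed)
    plate
  })
}

#' Simulate a KCl titration for z' calibration
#'
#' Per cell and concentration, 1/(dff0 + 1) = (Kx/Kr)^{z'} (1 + eps) with
#' eps ~ Normal(0, noise_cv).
#'
#' @param z_prime True dye-sensitivity exponent (nonzero).
#' @param kx External K+ concentrations in mM (default the 5.4-25 mM series).
#' @param kr Reference concentration in mM (default 5.4).
#' @param n_cells Cells imaged per concentration (default 50).
#' @param noise_cv Multiplicative noise CV on the intensity ratio.
#' @param seed RNG seed.
#' @return A [titration_series()].
#' @export
simulate_titration <- function(z_prime = -0.64, kx = c(5.4, 10, 15, 20, 25),
                               kr = 5.4, n_cells = 50L, noise_cv = 0.05,
                               seed = NULL) {
  check_scalar(z_prime, "z_prime")
  if (z_prime == 0) ntk_abort("ntk_domain_error", "z_prime must be nonzero")
  if (!any(abs(kx - kr) < 1e-12)) {
    ntk_abort("ntk_domain_error", "kx must include the reference kr")
  }
  with_seed(seed, {
    pts <- do.call(rbind, lapply(kx, function(k) {
      ratio <- (k / kr)^z_prime * (1 + stats::rnorm(n_cells, 0, noise_cv))
      if (any(ratio <= 0)) {
        ntk_abort("ntk_domain_error",
                  "noise produced nonpositive intensity ratio; rejected")
      }
      data.frame(kx = k, cell = seq_len(n_cells), dff0 = 1 / ratio - 1)
    }))
    titration_series(pts, kr = kr)
  })
}
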