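# Confocal z-stack profiling: gel thickness from the axial fluorescence
# profile of the fluorescein-stained gel (green channel), indentation depth
# from a surface-elevation map of the red bead layer deposited on the gel.
#
# Conventions: arrays are indexed (z, y, x); voxel indices are 0-based in the
# public axial-scale API; z positions are slice centres in micrometres;
# slice 0 is closest to the objective (well bottom). Lengths are micrometres
# throughout this module and converted to metres only at the mechanics
# boundary.

#' Two-channel confocal z-stack
#'
#' @param green,red 3-D intensity arrays with dimensions (z, y, x); green is
#'   the fluorescein-stained gel volume, red the surface bead layer.
#' @param xy_pixel_size Lateral pixel size in micrometres.
#' @param z_step Nominal axial step in micrometres.
#' @param z_origin Physical z position of slice 0 in micrometres (default 0);
#'   nonzero for stacks that image only the surface region.
#' @param refractive_index Immersion refractive index (default 1.33, water).
#' @param z_corrected Logical; `TRUE` (default) means the declared z-step is
#'   already index-corrected by the acquisition software, so no further
#'   refractive-index scaling is applied. Set `FALSE` to multiply nominal
#'   steps by the refractive index on the axial scale.
#' @return Object of class `z_stack`.
#' @export
z_stack <- function(green, red, xy_pixel_size, z_step, z_origin = 0,
                    refractive_index = 1.33, z_corrected = TRUE) {
  stopifnot(is.array(green), is.array(red),
            length(dim(green)) == 3L, identical(dim(green), dim(red)))
  check_scalar(xy_pixel_size, "xy_pixel_size", positive = TRUE)
  check_scalar(z_step, "z_step", positive = TRUE)
  check_scalar(z_origin, "z_origin", nonnegative = TRUE)
  check_scalar(refractive_index, "refractive_index", positive = TRUE)
  if (refractive_index < 1) {
    ntk_abort("ntk_domain_error", "refractive_index must be >= 1")
  }
  structure(
    list(green = green, red = red, xy_pixel_size = xy_pixel_size,
         z_step = z_step, z_origin = z_origin,
         refractive_index = refractive_index,
         z_corrected = isTRUE(z_corrected)),
    class = "z_stack"
  )
}

#' @export
print.z_stack <- function(x, ...) {
  d <- dim(x$green)
  cat(sprintf(
    "<z_stack> %d slices x %d x %d px, z-step %.3g um, pixel %.3g um\n",
    d[1], d[2], d[3], x$z_step, x$xy_pixel_size))
  invisible(x)
}

#' Axial position of a z-slice
#'
#' Maps a 0-based slice index to a physical z position. When the metadata
#' declares steps already index-corrected (the default) the scale factor is 1;
#' otherwise nominal steps are multiplied by the refractive index (mismatch
#' between immersion and sample media stretches the optical axial scale).
#'
#' @param z_index 0-based slice index (vectorised).
#' @param z_step Nominal step in micrometres.
#' @param refractive_index Refractive index used when `corrected = FALSE`.
#' @param corrected Logical, see [z_stack()].
#' @return z position(s) in micrometres.
#' @export
axial_scale <- function(z_index, z_step, refractive_index = 1.33,
                        corrected = TRUE) {
  if (any(z_index < 0)) ntk_abort("ntk_domain_error", "z_index must be >= 0")
  scale <- if (isTRUE(corrected)) 1 else refractive_index
  z_index * z_step * scale
}

stack_z_positions <- function(stack) {
  nz <- dim(stack$green)[1]
  stack$z_origin + axial_scale(seq_len(nz) - 1, stack$z_step,
                               stack$refractive_index, stack$z_corrected)
}

#' Axial mean-intensity profile
#'
#' Mean intensity over (y, x) per slice for one channel, with physical z
#' positions attached.
#'
#' @param stack A [z_stack()].
#' @param channel `"green"` or `"red"`.
#' @return Object of class `axial_profile` with `z`, `intensity`, `channel`.
#' @export
axial_profile <- function(stack, channel = c("green", "red")) {
  stopifnot(inherits(stack, "z_stack"))
  channel <- match.arg(channel)
  arr <- stack[[channel]]
  nz <- dim(arr)[1]
  intensity <- rowMeans(matrix(arr, nrow = nz))
  structure(
    list(z = stack_z_positions(stack), intensity = intensity,
         channel = channel),
    class = "axial_profile"
  )
}

#' Gel thickness from an axial profile
#'
#' Smooths the profile with a centred moving average, takes the first
#' difference, and reads the gel bottom as the position of the maximum
#' positive derivative and the gel top as the position of the most negative
#' derivative; thickness is their separation. Each boundary position is the
#' derivative-weighted centroid of the contiguous half-max run around the
#' extremum. A profile whose maximum absolute
#' derivative is zero or below three times the median absolute derivative is
#' treated as containing no gel.
#'
#' @param profile An [axial_profile()] with at least 5 slices.
#' @param smoothing_window Moving-average window in slices (odd; default 3).
#' @return Object of class `thickness_result` with `h`, `z_bottom`, `z_top`,
#'   `channel`, `smoothing_window` (micrometres).
#' @export
thickness_from_profile <- function(profile, smoothing_window = 3L) {
  stopifnot(inherits(profile, "axial_profile"))
  n <- length(profile$intensity)
  if (n < 5L) ntk_abort("ntk_domain_error", "profile must have >= 5 slices")
  w <- as.integer(smoothing_window)
  if (w < 1L || w %% 2L == 0L) {
    ntk_abort("ntk_domain_error", "smoothing_window must be a positive odd integer")
  }
  s <- as.numeric(stats::filter(profile$intensity, rep(1 / w, w), sides = 2))
  keep <- !is.na(s)
  s <- s[keep]
  z <- profile$z[keep]
  dz <- diff(z)
  d <- diff(s) / dz
  z_mid <- (z[-1] + z[-length(z)]) / 2
  max_d <- max(abs(d))
  if (max_d == 0 || max_d < 3 * stats::median(abs(d))) {
    ntk_abort("ntk_flat_profile_error",
              "no gel boundary detected: derivative below noise floor")
  }
  # boundary = derivative-weighted centroid of the contiguous half-max run
  # around each extremum: exact on noiseless boxcars (the smoothing spreads
  # one edge symmetrically over w transitions) and ~w/2 slices more precise
  # than a bare argmax under noise
  edge_centroid <- function(dd) {
    peak <- which.max(dd)
    run <- dd >= 0.5 * dd[peak]
    lo <- peak
    while (lo > 1L && run[lo - 1L]) lo <- lo - 1L
    hi <- peak
    while (hi < length(dd) && run[hi + 1L]) hi <- hi + 1L
    idx <- lo:hi
    sum(z_mid[idx] * dd[idx]) / sum(dd[idx])
  }
  z_bottom <- edge_centroid(d)
  z_top <- edge_centroid(-d)
  if (max(d) <= 0 || min(d) >= 0 || z_top <= z_bottom) {
    ntk_abort("ntk_inverted_boundary_error",
              sprintf("detected top (%.4g um) does not lie above bottom (%.4g um)",
                      z_top, z_bottom))
  }
  structure(
    list(h = z_top - z_bottom, z_bottom = z_bottom, z_top = z_top,
         channel = profile$channel, smoothing_window = w),
    class = "thickness_result"
  )
}

#' @export
print.thickness_result <- function(x, ...) {
  cat(sprintf("<thickness_result> h = %.4g um (%.4g -> %.4g um, %s channel)\n",
              x$h, x$z_bottom, x$z_top, x$channel))
  invisible(x)
}

#' Surface-elevation map from the bead channel
#'
#' For every (x, y) column, the gel surface is located as the
#' intensity-weighted axial centroid of the brightest contiguous blob (the
#' bead layer sits on the surface): slices at or above half the column maximum
#' that are contiguous with the argmax. Columns whose maximum falls below a
#' fraction of the channel-wide maximum are masked out.
#'
#' @param stack A [z_stack()].
#' @param channel Channel carrying the bead layer (default `"red"`).
#' @param detection_fraction Columns with max intensity below this fraction of
#'   the channel maximum are masked (default 0.1).
#' @return Object of class `surface_map`: `elevation` (y by x matrix, um, NA
#'   where masked), `mask`, `xy_pixel_size`, `z_step`.
#' @export
surface_map <- function(stack, channel = "red", detection_fraction = 0.1) {
  stopifnot(inherits(stack, "z_stack"))
  arr <- stack[[channel]]
  d <- dim(arr)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  z <- stack_z_positions(stack)
  m <- matrix(arr, nrow = nz)                       # z x (y*x), column-major
  cmax <- apply(m, 2L, max)
  global_max <- max(cmax)
  if (global_max <= 0) {
    ntk_abort("ntk_empty_surface_error", "channel carries no signal")
  }
  thr <- detection_fraction * global_max
  elev <- rep(NA_real_, ny * nx)
  for (j in which(cmax >= thr)) {
    col <- m[, j]
    peak <- which.max(col)
    half <- col >= 0.5 * col[peak]
    lo <- peak
    while (lo > 1L && half[lo - 1L]) lo <- lo - 1L
    hi <- peak
    while (hi < nz && half[hi + 1L]) hi <- hi + 1L
    idx <- lo:hi
    elev[j] <- sum(z[idx] * col[idx]) / sum(col[idx])
  }
  elevation <- matrix(elev, nrow = ny, ncol = nx)
  mask <- !is.na(elevation)
  if (mean(mask) < 0.05) {
    ntk_abort("ntk_empty_surface_error",
              sprintf("surface detected in only %.1f%% of columns (< 5%%)",
                      100 * mean(mask)))
  }
  structure(
    list(elevation = elevation, mask = mask,
         xy_pixel_size = stack$xy_pixel_size, z_step = stack$z_step),
    class = "surface_map"
  )
}

# 3x3 mean filter ignoring NAs (edge-padded).
smooth_map_3x3 <- function(mat) {
  ny <- nrow(mat); nx <- ncol(mat)
  acc <- matrix(0, ny, nx)
  cnt <- matrix(0, ny, nx)
  for (dy in -1:1) {
    for (dx in -1:1) {
      ys <- pmin(pmax(seq_len(ny) + dy, 1L), ny)
      xs <- pmin(pmax(seq_len(nx) + dx, 1L), nx)
      v <- mat[ys, xs, drop = FALSE]
      ok <- !is.na(v)
      v[!ok] <- 0
      acc <- acc + v
      cnt <- cnt + ok
    }
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Indentation depth from a surface map
#'
#' The undisturbed surface level is the median elevation over the outer
#' periphery annulus of the field; the indentation floor is the minimum of the
#' 3x3-smoothed elevation over the interior. Depth is their difference. A
#' depression whose minimum touches the field border indicates an off-centre
#' indenter and is rejected.
#'
#' @param map A [surface_map()].
#' @param periphery_fraction Fraction of the field taken as the baseline
#'   annulus (default 0.2, i.e. the outer 10% on each side).
#' @return Object of class `indentation_depth_result` with `delta`,
#'   `baseline_z`, `min_z` (um) and `center` (y, x pixel indices).
#' @export
indentation_depth <- function(map, periphery_fraction = 0.2) {
  stopifnot(inherits(map, "surface_map"))
  el <- map$elevation
  ny <- nrow(el); nx <- ncol(el)
  f <- periphery_fraction / 2
  yi <- seq_len(ny); xi <- seq_len(nx)
  periph <- outer(yi <= ny * f | yi > ny * (1 - f), rep(TRUE, nx)) |
    outer(rep(TRUE, ny), xi <= nx * f | xi > nx * (1 - f))
  if (!any(periph & map$mask) || !any(!periph & map$mask)) {
    ntk_abort("ntk_empty_surface_error",
              "periphery or interior contains no detected surface")
  }
  baseline <- stats::median(el[periph], na.rm = TRUE)
  sm <- smooth_map_3x3(el)
  gmin_idx <- arrayInd(which.min(sm), dim(sm))
  on_border <- gmin_idx[1] <= 1L || gmin_idx[1] >= ny ||
    gmin_idx[2] <= 1L || gmin_idx[2] >= nx
  if (on_border && baseline - min(sm, na.rm = TRUE) > 2 * map$z_step) {
    ntk_abort("ntk_edge_depression_error",
              "depression minimum touches the field border: indenter not centred")
  }
  interior_vals <- sm
  interior_vals[periph] <- NA_real_
  min_z <- min(interior_vals, na.rm = TRUE)
  center <- arrayInd(which.min(interior_vals), dim(sm))
  structure(
    list(delta = max(baseline - min_z, 0), baseline_z = baseline,
         min_z = min_z, center = c(y = center[1], x = center[2])),
    class = "indentation_depth_result"
  )
}

#' @export
print.indentation_depth_result <- function(x, ...) {
  cat(sprintf(
    "<indentation_depth_result> delta = %.4g um (baseline %.4g, min %.4g um)\n",
    x$delta, x$baseline_z, x$min_z))
  invisible(x)
}

#' XZ / YZ cross-section of a stack channel
#'
#' Extracts a single axial cross-section for visual inspection, mirroring the
#' microscope software's XZ/YZ views.
#'
#' @param stack A [z_stack()].
#' @param channel `"green"` or `"red"`.
#' @param axis `"xz"` (fixed y row) or `"yz"` (fixed x column).
#' @param index 1-based row/column index; defaults to the field centre.
#' @return A matrix (z in rows).
#' @export
cross_section <- function(stack, channel = c("green", "red"),
                          axis = c("xz", "yz"), index = NULL) {
  stopifnot(inherits(stack, "z_stack"))
  channel <- match.arg(channel)
  axis <- match.arg(axis)
  arr <- stack[[channel]]
  d <- dim(arr)
  if (axis == "xz") {
    if (is.null(index)) index <- ceiling(d[2] / 2)
    arr[, index, ]
  } else {
    if (is.null(index)) index <- ceiling(d[3] / 2)
    arr[, , index]
  }
}

#' Stack-processing configuration
#'
#' @param smoothing_window Axial smoothing window (slices) for the thickness
#'   profile.
#' @param periphery_fraction Baseline annulus fraction for depth measurement.
#' @param detection_fraction Bead-detection threshold for [surface_map()].
#' @export
stack_config <- function(smoothing_window = 3L, periphery_fraction = 0.2,
                         detection_fraction = 0.1) {
  structure(
    list(smoothing_window = as.integer(smoothing_window),
         periphery_fraction = periphery_fraction,
         detection_fraction = detection_fraction),
    class = "stack_config"
  )
}

#' Measure gel thickness and indentation depth from one stack
#'
#' Thickness h comes from the green-channel axial profile; depth delta from
#' the red-channel surface map.
#'
#' @param stack A [z_stack()] with both channels.
#' @param config A [stack_config()].
#' @return List with `thickness` and `indentation` results.
#' @export
measure_stack <- function(stack, config = stack_config()) {
  th <- thickness_from_profile(axial_profile(stack, "green"),
                               config$smoothing_window)
  sm <- surface_map(stack, "red", config$detection_fraction)
  dp <- indentation_depth(sm, config$periphery_fraction)
  list(thickness = th, indentation = dp)
}

#' Measure a simulated indentation scene
#'
#' A scene pairs a coarse full-height stack (for thickness) with a fine stack
#' of the surface region (for depth), as acquired in practice with 5 um and
#' 1 um steps respectively.
#'
#' @param scene A scene from [simulate_indentation_scene()] (or any list with
#'   `thickness_stack` and `indent_stack`).
#' @param config A [stack_config()].
#' @return List with `thickness`, `indentation`, and `h_um` / `delta_um`
#'   scalars.
#' @export
measure_scene <- function(scene, config = stack_config()) {
  th <- thickness_from_profile(axial_profile(scene$thickness_stack, "green"),
                               config$smoothing_window)
  sm <- surface_map(scene$indent_stack, "red", config$detection_fraction)
  dp <- indentation_depth(sm, config$periphery_fraction)
  list(thickness = th, indentation = dp, h_um = th$h, delta_um = dp$delta)
}
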