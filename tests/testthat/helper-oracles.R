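# Independent oracles, written as single closed-form expressions separate
# from the production code paths.

# Buoyant sphere weight, plain arithmetic.
oracle_load <- function(R, rho_s, rho_m = 1000, g = 9.81) {
  (4 / 3) * pi * R^3 * (rho_s - rho_m) * g
}

# Full thin-film pipeline in one expression. Returns NA when the correction
# denominator is non-positive.
oracle_modified_hertz <- function(F, R, delta, h, nu = 0.5,
                                  grouping = "printed") {
  E_h <- 3 * (1 - nu^2) * F / (4 * R^0.5 * delta^1.5)
  w <- (R * delta / h^2)^0.5
  a <- if (grouping == "printed") {
    10.05 - 0.63 * (h / R) * (3.1 + h^2 / R^2)
  } else {
    (10.05 - 0.63 * h / R) / (3.1 + h^2 / R^2)
  }
  b <- 4.8 - 4.23 * h^2 / R^2
  den <- 1 + 1.15 * w^(1 / 3) + a * w + b * w^2
  if (den <= 1e-9) return(NA_real_)
  E_h * (1 + 2.3 * w) / den
}

# Sample one random (indenter, h, delta) geometry inside the printed validity
# ranges; returns the draw whether or not the correction denominator is
# positive (callers filter with the oracle).
sample_valid_geometry <- function() {
  cat_ <- ntk::indenter_catalog()
  ind <- cat_[[sample(length(cat_), 1)]]
  r_over_h <- runif(1, 0.3, 12.7)
  h <- ind$radius / r_over_h
  d_over_h <- runif(1, 1e-4, min(0.6, r_over_h))
  list(indenter = ind, h = h, delta = d_over_h * h)
}

# Build a minimal valid plate for membrane tests: one background well at f0
# plus the supplied sample wells.
make_plate <- function(sample_wells, f0_reads = rep(200, 25)) {
  wells <- c(sample_wells,
             list(BG1 = ntk::well_read(f0_reads,
                                       role = "dye_only_background")))
  ntk::plate_read(wells)
}
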