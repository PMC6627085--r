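# Confocal stack profiling: axial scale, profiles, thickness, surface maps,
# indentation depth, and the composed measurement.

make_boxcar_stack <- function(nz = 150, occupied = 21:120, step = 1,
                              value = 1000, ny = 8, nx = 8) {
  g <- array(0, dim = c(nz, ny, nx))
  g[occupied, , ] <- value
  z_stack(g, array(0 * g, dim = dim(g)) + 0, xy_pixel_size = 1, z_step = step)
}

test_that("axial_scale maps indices to physical positions", {
  expect_identical(axial_scale(0, 1), 0)
  expect_identical(axial_scale(10, 1, corrected = TRUE), 10)
  expect_equal(axial_scale(10, 1, 1.33, corrected = FALSE), 13.3,
               tolerance = 1e-12)
  expect_error(axial_scale(-1, 1), class = "ntk_domain_error")
})

test_that("axial_profile averages each slice over (y, x)", {
  st <- make_boxcar_stack()
  p <- axial_profile(st, "green")
  expect_identical(p$intensity[21:120], rep(1000, 100))
  expect_identical(p$intensity[c(1:20, 121:150)], rep(0, 50))
  expect_identical(p$z, as.numeric(0:149))
  # constant stack -> constant profile
  st2 <- z_stack(array(7, c(10, 4, 4)), array(7, c(10, 4, 4)), 1, 1)
  expect_identical(axial_profile(st2, "red")$intensity, rep(7, 10))
})

test_that("thickness is exact to one slice on noiseless slabs at any position", {
  cases <- list(c(21, 120), c(5, 60), c(80, 145), c(40, 42))
  for (cs in cases) {
    st <- make_boxcar_stack(occupied = cs[1]:cs[2])
    th <- thickness_from_profile(axial_profile(st, "green"))
    true_h <- cs[2] - cs[1] + 1
    expect_lt(abs(th$h - true_h), 1 + 1e-9)
    expect_gt(th$z_top, th$z_bottom)
  }
  # 5 um steps scale the answer accordingly
  st5 <- make_boxcar_stack(nz = 100, occupied = 11:30, step = 5)
  th5 <- thickness_from_profile(axial_profile(st5, "green"))
  expect_lt(abs(th5$h - 100), 5 + 1e-9)
})

test_that("thickness tolerates 5% noise within +/- 2 um (window 5)", {
  set.seed(301)
  true_h <- 100
  errs <- replicate(60, {
    p <- structure(
      list(z = as.numeric(0:149),
           intensity = pmax(ifelse(0:149 %in% 21:120, 1000, 0) *
                              (1 + rnorm(150, 0, 0.05)), 0),
           channel = "green"),
      class = "axial_profile")
    thickness_from_profile(p, smoothing_window = 5)$h - true_h
  })
  expect_lt(max(abs(errs)), 2 + 1e-9)
})

test_that("flat or empty profiles raise FlatProfileError", {
  p0 <- structure(list(z = as.numeric(0:49), intensity = rep(0, 50),
                       channel = "green"), class = "axial_profile")
  expect_error(thickness_from_profile(p0), class = "ntk_flat_profile_error")
  pc <- structure(list(z = as.numeric(0:49), intensity = rep(5, 50),
                       channel = "green"), class = "axial_profile")
  expect_error(thickness_from_profile(pc), class = "ntk_flat_profile_error")
  expect_error(
    thickness_from_profile(structure(list(z = 0:3, intensity = rep(1, 4),
                                          channel = "green"),
                                     class = "axial_profile")),
    class = "ntk_domain_error")
})

test_that("surface_map finds a flat bead layer and rejects empty channels", {
  st <- simulate_indent_stack(h_um = 110, delta_um = 0, R_um = 400,
                              z_step = 1, field_px = 32, noise_cv = 0)
  sm <- surface_map(st)
  expect_true(all(sm$mask))
  expect_lt(abs(median(sm$elevation) - 120), 1 + 1e-9)  # z0 + h = 120
  dark <- z_stack(st$green, array(0, dim(st$green)), st$xy_pixel_size,
                  st$z_step)
  expect_error(surface_map(dark), class = "ntk_empty_surface_error")
})

test_that("surface_map reproduces a spherical-cap depression within 1 z-step RMS", {
  st <- simulate_indent_stack(h_um = 300, delta_um = 100, R_um = 400,
                              z_step = 1, field_px = 48, noise_cv = 0,
                              z_lo_um = 150)
  sm <- surface_map(st)
  px <- st$xy_pixel_size
  n <- dim(st$green)[2]
  coords <- (seq_len(n) - (n + 1) / 2) * px
  r2 <- outer(coords^2, coords^2, `+`)
  a2 <- 100 * (2 * 400 - 100)
  z_top <- 310
  truth <- matrix(z_top, n, n)
  truth[r2 < a2] <- z_top - 100 + (400 - sqrt(400^2 - r2[r2 < a2]))
  rms <- sqrt(mean((sm$elevation - truth)^2, na.rm = TRUE))
  expect_lt(rms, 1)
})

test_that("indentation_depth recovers cap depth, is flat-safe and edge-aware", {
  flat <- surface_map(simulate_indent_stack(h_um = 110, delta_um = 0,
                                            R_um = 400, field_px = 32,
                                            noise_cv = 0))
  expect_equal(indentation_depth(flat)$delta, 0, tolerance = 1e-9)
  cap <- surface_map(simulate_indent_stack(h_um = 300, delta_um = 100,
                                           R_um = 400, field_px = 64,
                                           noise_cv = 0, z_lo_um = 150))
  d <- indentation_depth(cap)
  expect_lt(abs(d$delta - 100), 1 + 1e-9)
  # cap centred on the field edge
  edge <- surface_map(simulate_indent_stack(
    h_um = 300, delta_um = 100, R_um = 400, field_px = 48, noise_cv = 0,
    z_lo_um = 150, field_um = 1200, center_offset_um = c(600, 0)))
  expect_error(indentation_depth(edge), class = "ntk_edge_depression_error")
})

test_that("depth estimate is translation-invariant and intensity-scale-invariant", {
  base <- simulate_indent_stack(h_um = 300, delta_um = 50, R_um = 400,
                                field_px = 48, noise_cv = 0, z_lo_um = 150,
                                field_um = 1200)
  d0 <- indentation_depth(surface_map(base))$delta
  shifted <- simulate_indent_stack(h_um = 300, delta_um = 50, R_um = 400,
                                   field_px = 48, noise_cv = 0, z_lo_um = 150,
                                   field_um = 1200,
                                   center_offset_um = c(100, -75))
  ds <- indentation_depth(surface_map(shifted))$delta
  expect_lt(abs(ds - d0), 0.5)
  scaled <- z_stack(base$green * 37, base$red * 37, base$xy_pixel_size,
                    base$z_step)
  expect_equal(indentation_depth(surface_map(scaled))$delta, d0,
               tolerance = 1e-9)
})

test_that("deeper caps yield strictly increasing depth estimates", {
  depths <- vapply(c(25, 50, 100, 200), function(d) {
    st <- simulate_indent_stack(h_um = 450, delta_um = d, R_um = 400,
                                field_px = 48, noise_cv = 0, z_lo_um = 200)
    indentation_depth(surface_map(st))$delta
  }, numeric(1))
  expect_true(all(diff(depths) > 0))
})

test_that("measure_stack and measure_scene recover (h, delta) from one scene", {
  st <- simulate_indent_stack(h_um = 120, delta_um = 30, R_um = 400,
                              z_step = 1, field_px = 32, noise_cv = 0)
  m <- measure_stack(st)
  expect_lt(abs(m$thickness$h - 120), 1 + 1e-9)
  expect_lt(abs(m$indentation$delta - 30), 1 + 1e-9)
  sc <- simulate_indentation_scene(250, noise_cv = 0, seed = 5)
  ms <- measure_scene(sc)
  expect_lt(abs(ms$h_um - sc$truth$h_true_um), 5 + 1e-9)       # 1 coarse slice
  expect_lt(abs(ms$delta_um - sc$truth$delta_true_um), 1 + 1e-9) # 1 fine slice
})
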