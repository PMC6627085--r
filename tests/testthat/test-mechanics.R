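# Indentation mechanics: buoyant load, Hertz and thin-film moduli, validity
# domain, composition, inversion, replicate summaries.

test_that("buoyant_load matches hand arithmetic and flags floating spheres", {
  si <- indenter_catalog("si3n4_1_32")
  wc <- indenter_catalog("wc_1_8")
  expect_equal(buoyant_load(si), oracle_load(si$radius, 3184), tolerance = 1e-12)
  expect_equal(buoyant_load(si), 5.61e-6, tolerance = 1e-3)
  expect_equal(buoyant_load(wc), oracle_load(wc$radius, 15630), tolerance = 1e-12)
  expect_equal(buoyant_load(wc), 2.40e-3, tolerance = 5e-3)
  expect_error(buoyant_load(indenter_spec("foam", 1e-3, 500)),
               class = "ntk_floating_indenter_error")
  expect_error(buoyant_load(indenter_spec("neutral", 1e-3, 1000)),
               class = "ntk_floating_indenter_error")
})

test_that("hertz_modulus evaluates the closed form with delta^{3/2}", {
  si <- indenter_catalog("si3n4_1_32")
  F <- buoyant_load(si)
  E <- hertz_modulus(F, si$radius, 1e-4, nu = 0.5)
  expect_equal(E, 158.4, tolerance = 1e-3)
  # inversion cross-check: F = (4/3) E/(1-nu^2) R^{1/2} delta^{3/2}
  expect_equal((4 / 3) * E / (1 - 0.25) * sqrt(si$radius) * (1e-4)^1.5, F,
               tolerance = 1e-12)
  # linear in F; (1 - nu^2) factor
  expect_identical(hertz_modulus(2 * F, si$radius, 1e-4), 2 * E)
  expect_equal(hertz_modulus(F, si$radius, 1e-4, nu = 0) /
                 hertz_modulus(F, si$radius, 1e-4, nu = 0.5),
               1 / 0.75, tolerance = 1e-12)
  expect_error(hertz_modulus(F, si$radius, 0), class = "ntk_domain_error")
  expect_error(hertz_modulus(-1, si$radius, 1e-4), class = "ntk_domain_error")
})

test_that("omega_param is (R delta / h^2)^{1/2}", {
  expect_identical(omega_param(1e-3, 0, 1e-3), 0)
  expect_equal(omega_param(2e-3, 2e-3, 2e-3), 1, tolerance = 1e-12)
  expect_equal(omega_param(3.96875e-4, 1e-4, 1.3e-3), 0.1533, tolerance = 1e-3)
  expect_error(omega_param(1e-3, 1e-4, 0), class = "ntk_domain_error")
})

test_that("film_coefficients supports both groupings of the flattened text", {
  R <- 3.96875e-4
  co <- film_coefficients(R, R, "printed")
  expect_equal(co$alpha, 10.05 - 0.63 * 4.1, tolerance = 1e-12)  # 7.467
  expect_equal(co$beta, 0.57, tolerance = 1e-12)
  cf <- film_coefficients(R, R, "fraction")
  expect_equal(cf$alpha, 9.42 / 4.1, tolerance = 1e-12)          # ~2.298
  expect_equal(cf$beta, 0.57, tolerance = 1e-12)
  # finite for any positive geometry
  for (hr in c(1e-3, 0.1, 1, 5, 50)) {
    for (g in c("printed", "fraction")) {
      co <- film_coefficients(R, hr * R, g)
      expect_true(is.finite(co$alpha) && is.finite(co$beta))
    }
  }
})

test_that("modified_hertz_modulus reproduces the worked example and guards the denominator", {
  expect_identical(modified_hertz_modulus(158.4, 0, 7.467, 0.57), 158.4)
  si <- indenter_catalog("si3n4_1_32")
  R <- si$radius
  E_h <- hertz_modulus(buoyant_load(si), R, 1e-4)
  w <- omega_param(R, 1e-4, R)
  expect_equal(w, 0.50196, tolerance = 1e-4)
  co <- film_coefficients(R, R, "printed")
  E_m <- modified_hertz_modulus(E_h, w, co$alpha, co$beta)
  expect_equal(E_m / E_h, 0.3711, tolerance = 1e-3)
  expect_equal(E_m, 58.8, tolerance = 2e-3)
  # printed grouping, h/R = 3.3, delta/h = 0.08: denominator is negative
  # inside the validity domain (R/h = 0.303)
  h <- 3.3 * R; delta <- 0.08 * h
  co2 <- film_coefficients(R, h, "printed")
  expect_true(check_validity(R, delta, h)$valid)
  expect_error(
    modified_hertz_modulus(hertz_modulus(buoyant_load(si), R, delta),
                           omega_param(R, delta, h), co2$alpha, co2$beta),
    class = "ntk_nonpositive_denominator_error")
})

test_that("check_validity reproduces the printed inequalities, inclusive at bounds", {
  h <- 1.3e-3
  expect_true(check_validity(0.3 * h, 0.1 * h, h)$valid)     # R/h = 0.3 boundary
  v <- check_validity(0.29 * h, 0.1 * h, h)
  expect_false(v$valid)
  expect_true("R/h >= 0.3" %in% v$violations)
  v2 <- check_validity(1 * h, 0.61 * h, h)
  expect_false(v2$valid)
  expect_true("delta/h <= min(0.6, R/h)" %in% v2$violations)
  expect_true(check_validity(12.7 * h, 0.6 * h, h)$valid)    # upper boundaries
  expect_false(check_validity(12.8 * h, 0.1 * h, h)$valid)
  # pure and total: flags match direct evaluation on random draws, no errors
  set.seed(42)
  for (i in 1:50) {
    r_h <- runif(1, 0.1, 15); d_h <- runif(1, 0, 1)
    v <- check_validity(r_h * h, d_h * h, h)
    expect_identical(v$valid,
                     (r_h >= 0.3 - 1e-9) && (r_h <= 12.7 * (1 + 1e-9)) &&
                       (d_h <= min(0.6, r_h) + 1e-8))
  }
})

test_that("modulus_from_measurement composes the pipeline and carries audit fields", {
  si <- indenter_catalog("si3n4_1_32")
  res <- modulus_from_measurement(si, medium_spec(),
                                  gel_measurement(si$radius, 1e-4))
  expect_s3_class(res, "modulus_result")
  expect_equal(res$E_hertz, 158.4, tolerance = 1e-3)
  expect_equal(res$E_modified, 58.8, tolerance = 2e-3)
  expect_true(res$valid)
  expect_equal(res$omega, 0.50196, tolerance = 1e-4)
  expect_error(modulus_from_measurement(si, medium_spec(),
                                        gel_measurement(1e-3, 0)),
               class = "ntk_domain_error")
  # out-of-range geometry is flagged, not fatal
  res2 <- modulus_from_measurement(si, medium_spec(),
                                   gel_measurement(si$radius / 0.29, 1e-5))
  expect_false(res2$valid)
  expect_true(length(res2$violations) > 0)
})

test_that("scale covariance: multiplying F by k scales both moduli by k", {
  si <- indenter_catalog("si3n4_1_32")
  h <- si$radius; delta <- 1e-4
  base_F <- buoyant_load(si)
  for (k in c(0.5, 2, 10)) {
    # scale the load by scaling the density contrast
    rho_k <- 1000 + k * (si$density - 1000)
    ind_k <- indenter_spec("scaled", si$diameter, rho_k)
    r1 <- modulus_from_measurement(si, medium_spec(), gel_measurement(h, delta))
    r2 <- modulus_from_measurement(ind_k, medium_spec(), gel_measurement(h, delta))
    expect_equal(r2$force / r1$force, k, tolerance = 1e-12)
    expect_equal(r2$E_hertz / r1$E_hertz, k, tolerance = 1e-12)
    expect_equal(r2$E_modified / r1$E_modified, k, tolerance = 1e-12)
    expect_identical(r2$omega, r1$omega)
    expect_identical(r2$alpha, r1$alpha)
  }
})

test_that("thick-sample limit: E_modified -> E_hertz as omega -> 0", {
  # convergence is governed by the 1.15 omega^{1/3} term, so the deviation
  # from 1 at omega = 1e-6 is ~1.15e-2, not 1e-3 (see the acceptance suite
  # for the verbatim, stricter criterion, left red as a documented defect)
  omegas <- 10^seq(-4, -12, by = -2)
  ratios <- vapply(omegas,
                   function(w) modified_hertz_modulus(100, w, 7.467, 0.57) / 100,
                   numeric(1))
  expect_true(all(diff(abs(ratios - 1)) < 0))      # monotone approach to 1
  expect_equal(1 - ratios[2], 1.15 * (1e-6)^(1 / 3), tolerance = 5e-2)
  expect_equal(ratios[length(ratios)], 1, tolerance = 1e-3)  # omega = 1e-12
  expect_identical(modified_hertz_modulus(100, 0, 7.467, 0.57), 100)
})

test_that("pipeline agrees with the single-expression oracle", {
  set.seed(7)
  med <- medium_spec()
  n_ok <- 0
  while (n_ok < 100) {
    g <- sample_valid_geometry()
    exp_E <- oracle_modified_hertz(oracle_load(g$indenter$radius,
                                               g$indenter$density),
                                   g$indenter$radius, g$delta, g$h)
    if (is.na(exp_E)) {
      expect_error(
        modulus_from_measurement(g$indenter, med,
                                 gel_measurement(g$h, g$delta)),
        class = "ntk_nonpositive_denominator_error")
      next
    }
    res <- modulus_from_measurement(g$indenter, med,
                                    gel_measurement(g$h, g$delta))
    expect_equal(res$E_modified, exp_E, tolerance = 1e-12)
    n_ok <- n_ok + 1
  }
})

test_that("invert_indentation round-trips and is monotone on its bracket", {
  si <- indenter_catalog("si3n4_1_32")
  med <- medium_spec()
  h <- 400e-6
  dom <- indentation_domain(si, med, h)
  expect_true(all(diff(dom$E) < 0))      # grid pre-scan is strictly decreasing
  for (E_true in c(100, 250, 700)) {
    d <- invert_indentation(E_true, si, med, h)
    back <- modulus_from_measurement(si, med, gel_measurement(h, d))$E_modified
    expect_equal(back, E_true, tolerance = 1e-9)
  }
  # larger target -> smaller depth
  d1 <- invert_indentation(150, si, med, h)
  d2 <- invert_indentation(600, si, med, h)
  expect_true(d2 < d1)
  # unreachable stiffness
  expect_error(invert_indentation(1e16, si, med, h),
               class = "ntk_no_root_error")
})

test_that("summarize_replicates reports mean, sample SD, SEM and n", {
  si <- indenter_catalog("si3n4_1_32")
  mk <- function(E) {
    d <- invert_indentation(E, si, medium_spec(), 400e-6)
    modulus_from_measurement(si, medium_spec(), gel_measurement(400e-6, d))
  }
  res <- lapply(c(100, 110, 120), mk)
  s <- summarize_replicates(res)
  row <- s[s$metric == "E_modified", ]
  expect_equal(row$mean, 110, tolerance = 1e-6)
  expect_equal(row$sd, 10, tolerance = 1e-5)
  expect_equal(row$sem, 10 / sqrt(3), tolerance = 1e-5)
  expect_identical(row$n, 3L)
  same <- summarize_replicates(lapply(c(100, 100, 100), mk))
  expect_equal(same[1, "sd"], 0, tolerance = 1e-6)
  expect_warning(s1 <- summarize_replicates(res[1]),
                 class = "ntk_single_replicate_warning")
  expect_true(is.na(s1[1, "sd"]))
  expect_error(summarize_replicates(list()), class = "ntk_domain_error")
})
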