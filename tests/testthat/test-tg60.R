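test_that("line-source geometry function matches hand values and limits", {
  # transverse reference geometry: beta = 2 atan(1.125)
  expect_equal(geometry_function_line(2, 90), 2 * atan(1.125) / 9,
               tolerance = 1e-12)
  expect_equal(geometry_function_line(2, 90), 0.187590, tolerance = 1e-5)
  # on-axis closed form
  expect_equal(geometry_function_line(5, 0), 1 / (25 - 4.5^2 / 4),
               tolerance = 1e-12)
  expect_equal(geometry_function_line(5, 0), 0.050157, tolerance = 1e-4)
  # point-source limit
  expect_equal(geometry_function_line(1000, 37) * 1000^2, 1, tolerance = 1e-4)
  # inside the active line is undefined
  expect_error(geometry_function_line(2, 0), "source line")
})

test_that("geometry function agrees with the brute-force line integral", {
  set.seed(314)
  r <- runif(100, 1, 12)
  th <- runif(100, 2, 178)
  for (i in seq_along(r)) {
    expect_equal(geometry_function_line(r[i], th[i]),
                 gl_brute_force(r[i], th[i]),
                 tolerance = 1e-6)
  }
})

test_that("radial dose function reproduces the printed gL values", {
  t4 <- load_reference_table("table4_radial_dose_rate")$data
  gl <- radial_dose_function(data.frame(r_mm = t4$r_mm, dose_rate = t4$MCNP5))
  expect_equal(gl$gL[gl$r_mm == 2.0], 1)
  expect_equal(gl$gL[gl$r_mm == 1.0], 1.100, tolerance = 1e-3)
  expect_equal(round(gl$gL[gl$r_mm == 5.0], 3), 0.374)
  expect_error(radial_dose_function(data.frame(r_mm = c(1, 3), dose_rate = c(2, 1))),
               "reference radius")
})

test_that("printed dose-rate and gL tables are mutually consistent except at 1.5 mm", {
  t4 <- load_reference_table("table4_radial_dose_rate")$data
  t6 <- load_reference_table("table6_gL")$data
  gl <- radial_dose_function(data.frame(r_mm = t4$r_mm, dose_rate = t4$MCNP5))
  dev <- abs(gl$gL - t6$MCNP5)
  expect_lt(max(dev[t4$r_mm != 1.5]), 1e-3)
  # the r = 1.5 mm row of the printed tables disagrees with itself by
  # ~0.004 through the line-source geometry function (in every code
  # column); it is the one printed inconsistency
  expect_gt(dev[t4$r_mm == 1.5], 1e-3)
  expect_lt(dev[t4$r_mm == 1.5], 5e-3)
})

test_that("quintic refit of the printed gL is essentially exact", {
  t6 <- load_reference_table("table6_gL")$data
  fit <- fit_radial_polynomial(data.frame(r_mm = t6$r_mm, gL = t6$MCNP5))
  expect_gte(fit$R, 0.999)
  # printed coefficients evaluate to ~1.002 at the reference radius
  eq1 <- load_reference_table("eq1_coefficients")$data
  a <- eq1$value[match(paste0("a", 0:5), eq1$name)]
  expect_equal(round(sum(a * 2^(0:5)), 3), 1.002)
})

test_that("fitting exact quintic data recovers its coefficients", {
  a_true <- c(1.02, 0.19, -0.13, 0.017, -7e-4, 4e-6)
  r <- seq(1, 10, by = 0.5)
  gl <- data.frame(r_mm = r, gL = drop(outer(r, 0:5, `^`) %*% a_true))
  fit <- fit_radial_polynomial(gl)
  expect_equal(unname(fit$coefficients), a_true, tolerance = 1e-8)
  expect_error(fit_radial_polynomial(gl[1:4, ]), "at least")
})

test_that("anisotropy extraction is normalized and masks the seed shadow", {
  Fm <- anisotropy_2d(shared_sim()$grid)
  expect_true(all(abs(Fm["90", ] - 1) < 1e-12, na.rm = TRUE))
  # cells behind the seed at small radius are undefined, not zero
  expect_true(is.na(Fm["0", "1"]))
  # off-axis anisotropy near the printed table at stochastic tolerance
  expect_equal(unname(Fm["40", "4"]), 1.071, tolerance = 0.10)
})

test_that("1D anisotropy is the solid-angle mean and is bounded by F", {
  # isotropic synthetic grid
  iso <- synthetic_grid()
  phi <- anisotropy_1d(iso, radii_mm = c(3, 5, 8))
  expect_equal(phi$phi_an, c(1, 1, 1), tolerance = 1e-12)
  # on the simulated grid phi_an, being a solid-angle-weighted mean of
  # the relative dose D(r,theta)/D(r,90), lies between its extremes
  sim <- yasdose:::.mirror_symmetrize(shared_sim()$grid)
  phi_sim <- anisotropy_1d(sim, radii_mm = c(4, 5, 6))
  for (r in c(4, 5, 6)) {
    thetas <- seq(1, 179, by = 2) # band midpoints
    d90 <- yasdose:::.grid_point_dose(sim, r, 90)
    rel <- vapply(thetas, function(th) {
      yasdose:::.grid_point_dose(sim, r, th)
    }, numeric(1)) / d90
    p <- phi_sim$phi_an[phi_sim$r_mm == r]
    expect_gte(p, min(rel, na.rm = TRUE) - 1e-9)
    expect_lte(p, max(rel, na.rm = TRUE) + 1e-9)
  }
  hemi <- synthetic_grid()
  hemi$grid$n_theta <- hemi$grid$n_theta / 2L  # only one hemisphere scored
  expect_error(anisotropy_1d(hemi), "polar")
})

test_that("quadrature over the printed F table recovers the printed phi_an", {
  t7 <- load_reference_table("table7_F")$data
  phi <- load_reference_table("table7_phi_an")$data
  for (r in c(3.0, 5.0, 7.0)) {
    col <- t7[[paste0("r", format(r, nsmall = 1))]]
    got <- phi_an_from_F(col, r, t7$theta_deg)
    expect_equal(got, phi$phi_an[phi$r_mm == r], tolerance = 0.05)
  }
})

test_that("reference dose rate comes from the cell containing (2 mm, 90 deg)", {
  t4 <- load_reference_table("table4_radial_dose_rate")$data
  expect_identical(
    reference_dose_rate(data.frame(r_mm = t4$r_mm, dose_rate = t4$MCNP5)),
    5.0542)
  # uniform synthetic grid of ones
  ones <- synthetic_grid(profile = function(r) rep(1, length(r)))
  expect_equal(reference_dose_rate(ones), 1)
  expect_error(reference_dose_rate(data.frame(r_mm = 1, dose_rate = 2)),
               "reference radius|2 mm")
})

test_that("TG-60 reconstruction interpolates the packaged tables", {
  p <- tg60_reference_params()
  expect_equal(dose_rate_tg60(p, 2, 90), 5.0542, tolerance = 1e-9)
  expect_equal(dose_rate_tg60(p, 1, 90), 15.18, tolerance = 5e-3)
  expect_equal(dose_rate_tg60(p, 5, 90), 0.3784, tolerance = 5e-3)
  expect_warning(out <- dose_rate_tg60(p, 11, 90), "outside")
  expect_true(is.na(out))
})

test_that("parameter-set validation enforces the protocol normalizations", {
  p <- tg60_reference_params()
  bad_gl <- p$gl_table
  bad_gl$gL <- bad_gl$gL * 1.01
  expect_error(tg60_parameter_set(p$ref_dose_rate, bad_gl, p$F_table),
               "normalized")
  bad_F <- p$F_table
  bad_F["90", 3] <- 1.05
  expect_error(tg60_parameter_set(p$ref_dose_rate, p$gl_table, bad_F),
               "transverse")
})

test_that("extract + reconstruct round-trips the simulated grid within 2%", {
  sim <- shared_sim()$grid
  params <- extract_tg60(sim)
  radii <- seq(2, 8, by = 0.5)
  thetas <- seq(20, 90, by = 10)
  for (th in thetas) {
    rec <- dose_rate_tg60(params, radii, th)
    direct <- vapply(radii, function(r) yasdose:::.grid_point_dose(
      yasdose:::.mirror_symmetrize(sim), r, th), numeric(1))
    expect_equal(rec, direct, tolerance = 0.02)
  }
})

test_that("TG-60 parameters serialize to JSON and back", {
  p <- tg60_reference_params()
  js <- tg60_to_json(p)
  back <- jsonlite::fromJSON(js)
  expect_equal(back$ref_dose_rate_cgy_h_uci, p$ref_dose_rate)
  expect_equal(back$fit$R, p$fit$R)
  expect_equal(back$gL$gL, p$gl_table$gL)
})
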