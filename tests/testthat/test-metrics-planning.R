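test_that("permanent implant dose integrates the decay curve", {
  # 0.0003 cGy/h/uCi at 10 mm x 5 mCi of 90Y, full decay
  expect_equal(permanent_implant_dose(0.0003 * 5000, 64.0), 1.38,
               tolerance = 0.005)
  # mean-lifetime integral for a unit dose rate
  expect_equal(permanent_implant_dose(1, 64.0), 0.9233, tolerance = 1e-4)
  # one half-life delivers half the lifetime dose
  expect_equal(permanent_implant_dose(1, 64.0, 64.0),
               permanent_implant_dose(1, 64.0) / 2, tolerance = 1e-12)
  # linear in the initial dose rate
  expect_equal(permanent_implant_dose(7, 64.0), 7 * permanent_implant_dose(1, 64.0),
               tolerance = 1e-12)
})

test_that("90% of the lifetime dose arrives at the cross-module t90", {
  lam <- decay_constant(64.0)
  t90 <- time_to_dose_fraction(lam, 0.9)
  expect_equal(permanent_implant_dose(1, 64.0, t90),
               0.9 * permanent_implant_dose(1, 64.0), tolerance = 1e-12)
})

test_that("contained-to-apparent ratio follows the self-absorption", {
  expect_equal(contained_to_apparent(0.3051), 1.4391, tolerance = 1e-4)
  expect_equal(round(contained_to_apparent(0.3051), 1), 1.4)
  expect_equal(contained_to_apparent(0), 1)
  expect_equal(contained_to_apparent(0.5), 2)
  expect_error(contained_to_apparent(1), "\\[0, 1\\)")
})

test_that("isodose contours nest and are self-consistent with the profile", {
  sim <- shared_sim()$grid
  tp <- transverse_profile(sim, radii_mm = c(2, 3, 5))
  lv <- tp$dose_rate
  cont <- isodose_contours(sim, lv)
  expect_length(cont, 3)
  # higher dose level lies strictly inside the lower one
  rmax <- vapply(cont, function(p) max(sqrt(p$y_mm^2 + p$z_mm^2)), numeric(1))
  expect_true(all(diff(rmax) > 0))
  # the level equal to the transverse dose at 3 mm crosses the
  # transverse axis at 3 mm
  p3 <- cont[[2]]
  near_axis <- abs(p3$z_mm) < 0.15
  expect_true(any(near_axis))
  expect_equal(max(abs(p3$y_mm[near_axis])), 3.0, tolerance = 0.04)
})

test_that("a spherically symmetric field gives circular contours", {
  iso <- synthetic_grid(profile = function(r) exp(-r))
  cont <- isodose_contours(iso, exp(-4))
  p <- cont[[1]]
  rad <- sqrt(p$y_mm^2 + p$z_mm^2)
  ecc <- (max(rad) - min(rad)) / mean(rad)
  expect_lt(ecc, 0.02)
  expect_equal(mean(rad), 4, tolerance = 0.05)
})

test_that("out-of-range isodose levels warn and return empty polylines", {
  iso <- synthetic_grid(profile = function(r) exp(-r))
  expect_warning(cont <- isodose_contours(iso, 1e6), "dynamic range")
  expect_equal(nrow(cont[[1]]), 0)
})

test_that("multi-seed superposition reduces to the single-seed dose", {
  p <- tg60_reference_params()
  one <- implant_plan(data.frame(x_mm = 0, y_mm = 0, z_mm = 0,
                                 ux = 0, uy = 0, uz = 1, activity_mci = 1),
                      p)
  pt <- c(4, 0, 0)
  expect_equal(multi_seed_dose(one, pt),
               permanent_implant_dose(dose_rate_tg60(p, 4, 90) * 1000, 64.0),
               tolerance = 1e-12)
})

test_that("two identical seeds give exactly twice the midpoint dose", {
  p <- tg60_reference_params()
  two <- implant_plan(data.frame(x_mm = c(-5, 5), y_mm = 0, z_mm = 0,
                                 ux = 0, uy = 0, uz = 1,
                                 activity_mci = 1), p)
  one <- implant_plan(data.frame(x_mm = -5, y_mm = 0, z_mm = 0,
                                 ux = 0, uy = 0, uz = 1, activity_mci = 1), p)
  mid <- c(0, 0, 0)
  expect_equal(multi_seed_dose(two, mid), 2 * multi_seed_dose(one, mid),
               tolerance = 1e-12)
})

test_that("three collinear seeds match a brute-force superposition", {
  p <- tg60_reference_params()
  seeds <- data.frame(x_mm = c(-10, 0, 10), y_mm = 0, z_mm = 0,
                      ux = 0, uy = 0, uz = 1,
                      activity_mci = c(1, 2, 1.5))
  plan <- implant_plan(seeds, p)
  probe <- c(3, 2, 1)
  # independent summation oracle
  rate <- 0
  for (i in 1:3) {
    v <- probe - c(seeds$x_mm[i], 0, 0)
    r <- sqrt(sum(v^2))
    th <- acos(abs(v[3]) / r) * 180 / pi
    ri <- suppressWarnings(dose_rate_tg60(p, r, th))
    if (is.na(ri)) ri <- 0  # beyond the beta range of the far seed
    rate <- rate + ri * seeds$activity_mci[i] * 1000
  }
  expect_equal(multi_seed_dose(plan, probe),
               permanent_implant_dose(rate, 64.0), tolerance = 1e-12)
})

test_that("points inside a seed are rejected", {
  p <- tg60_reference_params()
  one <- implant_plan(data.frame(x_mm = 0, y_mm = 0, z_mm = 0,
                                 ux = 0, uy = 0, uz = 1, activity_mci = 1), p)
  expect_error(multi_seed_dose(one, c(0.1, 0, 1)), "inside seed")
  expect_error(implant_plan(data.frame(x_mm = 0, y_mm = 0, z_mm = 0,
                                       ux = 0, uy = 0, uz = 2,
                                       activity_mci = 1), p),
               "unit vectors")
})
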