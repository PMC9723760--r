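# Derived hydrochemical quantities and profile operations.

test_that("P* reproduces published spot values and is linear", {
  expect_equal(round(p_star(0.88, 9.82), 2), 0.27)
  expect_equal(round(p_star(0.64, 9.05), 2), 0.07)
  expect_equal(p_star(0, 0), 0)
  expect_true(is.na(p_star(NA, 1)))
  # linearity
  set.seed(8)
  p <- runif(10); n <- runif(10, 0, 20)
  expect_equal(p_star(2 * p, 2 * n), 2 * p_star(p, n))
  expect_equal(p_star(p + 1, n), p_star(p, n) + 1)
})

test_that("analyte censoring flags BDL without altering values", {
  expect_equal(censor_analyte(c(0.005, 0.02, 0.08), 0.01, 0.04),
               c("BDL", "DNQ", "quantified"))
  h <- hydro_table(tibble::tibble(
    cruise = "X", station = "1", depth_m = c(2, 30),
    temp_c = c(18, 12), salinity = c(33.4, 33.4),
    no3no2_umol_l = c(0.005, 9.82), po4_umol_l = c(0.09, 0.88),
    chl_ug_l = c(0.17, 0.9)))
  expect_equal(h$no3no2_status, c("BDL", "quantified"))
  expect_equal(h$no3no2_umol_l[1], 0.005) # raw value retained
  expect_equal(round(h$p_star[2], 2), 0.27)
})

test_that("depth integration is a surface-extended trapezoid", {
  expect_equal(depth_integrate(c(0, 100), c(5, 5)), 500)
  expect_equal(depth_integrate(c(0, 100), c(10, 0)), 500)
  # order invariance
  expect_equal(depth_integrate(c(100, 30, 0), c(0, 3, 10)),
               depth_integrate(c(0, 30, 100), c(10, 3, 0)))
  # surface extension: shallowest value carried to 0 m
  expect_equal(depth_integrate(c(10, 20), c(4, 4)), 80)
  # additive over contiguous intervals
  z <- c(0, 10, 40, 100); v <- c(8, 6, 3, 1)
  expect_equal(
    depth_integrate(z, v, z_max = 40) +
      depth_integrate(z[3:4], v[3:4]) - 40 * v[3],
    depth_integrate(z, v))
  # homogeneous of degree 1
  expect_equal(depth_integrate(z, 3 * v), 3 * depth_integrate(z, v))
  # truncation interpolates; extension requires opt-in
  expect_equal(depth_integrate(c(0, 100), c(10, 0), z_max = 50),
               10 * 50 - 0.5 * 5 * 50)
  expect_error(depth_integrate(c(0, 100), c(1, 1), z_max = 150),
               "extend")
  expect_equal(depth_integrate(c(0, 100), c(1, 1), z_max = 150,
                               extend = TRUE), 150)
  expect_error(depth_integrate(10, 5), ">= 2 depths")
  # copies/l integrate to copies/m2 with the 1000 factor
  expect_equal(depth_integrate(c(0, 100), c(5, 5), scale = 1000),
               5e5)
})

test_that("mixed-layer depth interpolates the threshold crossing", {
  flat <- mixed_layer_depth(c(2, 10, 30), c(25, 25, 25))
  expect_equal(flat$mld_m, 30)
  expect_equal(flat$flag, "unstratified")
  # two-layer density jump bracketed between 10 and 30 m: with a 1.0
  # jump and 0.125 threshold the crossing sits 12.5% into the interval
  two <- mixed_layer_depth(c(2, 10, 30), c(25, 25, 26))
  expect_equal(two$mld_m, 10 + 0.125 * 20)
  expect_equal(two$flag, "ok")
  # temperature criterion is two-sided
  tw <- mixed_layer_depth(c(2, 10, 30), c(18, 18, 14),
                          criterion = "temperature")
  expect_equal(tw$mld_m, 10 + 0.2 / 4 * 20)
  # threshold larger than the range: deepest, flagged
  big <- mixed_layer_depth(c(2, 30), c(25, 25.05))
  expect_equal(big$flag, "unstratified")
  expect_equal(big$mld_m, 30)
})

test_that("Redfield carbon equivalent is 106/16 per unit N", {
  expect_equal(redfield_c_equivalent(0), 0)
  expect_equal(redfield_c_equivalent(16), 106)
  expect_equal(round(redfield_c_equivalent(195), 1), 1291.9)
  expect_error(redfield_c_equivalent(-1), "non-negative")
})
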