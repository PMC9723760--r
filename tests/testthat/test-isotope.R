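# Isotope bookkeeping and bulk-rate estimation.

test_that("atom percent / ratio conversion is exact and invertible", {
  expect_equal(atom_percent_from_ratio(0), 0)
  expect_equal(atom_percent_from_ratio(1), 50)
  # natural-abundance ratio, closed form 100 r / (1 + r)
  expect_equal(atom_percent_from_ratio(0.0036765),
               100 * 0.0036765 / 1.0036765)
  expect_error(atom_percent_from_ratio(-0.1), "ratio")

  # round trip identity within 1e-12, and strict monotonicity
  set.seed(11)
  r <- sort(exp(runif(50, -8, 4)))
  a <- atom_percent_from_ratio(r)
  expect_true(all(a >= 0 & a < 100))
  expect_true(all(diff(a) > 0))
  expect_equal(ratio_from_atom_percent(a), r, tolerance = 1e-12)
})

test_that("source-pool mixing is the volume-weighted mean", {
  expect_equal(mix_source_pool(24.7, 0, 1.1, a_ambient = 0.3663),
               0.3663)
  expect_equal(mix_source_pool(5, 0.3, 0.9, a_ambient = 5), 5)
  expect_equal(mix_source_pool(24.7, 0.1, 1.1, a_ambient = 0.3663),
               (0.1 * 24.7 + 1.1 * 0.3663) / 1.2)
  # result always between the two end members
  set.seed(2)
  for (i in 1:20) {
    ae <- runif(1, 1, 50); aa <- runif(1, 0, 1)
    m <- mix_source_pool(ae, runif(1, 0, 0.5), runif(1, 0.5, 2), aa)
    expect_gte(m, aa)
    expect_lte(m, ae)
  }
  expect_error(mix_source_pool(5, 0, 0), "volume")
})

test_that("bulk mass balance reproduces the closed form and limits", {
  r <- bulk_nfr(0.3663, 0.5, 2.3941, pn_umol_l = 1, duration_d = 1)
  expect_equal(r$rate_nmol_l_d,
               (0.5 - 0.3663) / (2.3941 - 0.3663) * 1000)
  expect_equal(round(r$rate_nmol_l_d, 2), 65.93)
  expect_equal(r$status, "quantified") # noiseless: lod = mqr = 0

  # no enrichment -> zero rate, below detection
  r0 <- bulk_nfr(0.3663, 0.3663, 2.3941, 1, 1, sd_a_pn_ref = 5e-4)
  expect_equal(r0$rate_nmol_l_d, 0)
  expect_equal(r0$status, "BDL")

  # full labelling -> pn / duration
  rf <- bulk_nfr(0.3663, 2.3941, 2.3941, pn_umol_l = 0.8,
                 duration_d = 2)
  expect_equal(rf$rate_nmol_l_d, 0.8 * 1000 / 2)

  # negative enrichment: BDL, rate clamped at 0, raw signed kept
  rn <- bulk_nfr(0.3663, 0.36, 2.3941, 1, 1)
  expect_equal(rn$status, "BDL")
  expect_equal(rn$rate_nmol_l_d, 0)
  expect_lt(rn$rate_raw, 0)

  expect_error(bulk_nfr(2.5, 3, 2.3941, 1, 1), "undefined")
  expect_error(bulk_nfr(0.3663, 0.5, 2.3941, 1, 0), "duration")
})

test_that("bulk rate is monotone in its drivers and unit-consistent", {
  base <- bulk_nfr(0.3663, 0.6, 2.3941, 1, 1)$rate_nmol_l_d
  expect_gt(bulk_nfr(0.3663, 0.7, 2.3941, 1, 1)$rate_nmol_l_d, base)
  expect_gt(bulk_nfr(0.3663, 0.6, 2.3941, 2, 1)$rate_nmol_l_d, base)
  expect_lt(bulk_nfr(0.3663, 0.6, 5.0, 1, 1)$rate_nmol_l_d, base)
  # expressing the incubation in hours and renormalising to days gives
  # the identical daily rate
  per_day <- bulk_nfr(0.3663, 0.6, 2.3941, 1, duration_d = 0.5)
  per_hour <- bulk_nfr(0.3663, 0.6, 2.3941, 1, duration_d = 12 / 24)
  expect_equal(per_day$rate_nmol_l_d, per_hour$rate_nmol_l_d)
})

test_that("detection limits scale with reference SD and PN", {
  z <- nfr_detection_limits(0.3663, 2.3941, 1, 1, sd_a_pn_ref = 0)
  expect_equal(z$lod, 0)
  expect_equal(z$mqr, 0)

  l <- nfr_detection_limits(0.3663, 2.3941, 1, 1, sd_a_pn_ref = 5e-4)
  expect_equal(l$lod, 3 * 5e-4 / (2.3941 - 0.3663) * 1000)
  expect_equal(round(l$lod, 3), 0.740)
  expect_equal(l$mqr / l$lod, 10 / 3)

  l2 <- nfr_detection_limits(0.3663, 2.3941, 2, 1, sd_a_pn_ref = 5e-4)
  expect_equal(l2$lod, 2 * l$lod)
  l3 <- nfr_detection_limits(0.3663, 2.3941, 1, 1, sd_a_pn_ref = 1e-3)
  expect_equal(l3$lod, 2 * l$lod)
})

test_that("bulk estimator is unbiased under Gaussian atom% noise", {
  set.seed(314)
  true_rate <- 8.5
  a_n2 <- 2.3941
  a0 <- 0.3663
  pn <- 1
  nrep <- 2000
  delta <- true_rate * (a_n2 - a0) / (pn * 1000)
  a_final <- a0 + delta + rnorm(nrep, 0, 5e-4)
  a_t0 <- a0 + rnorm(nrep, 0, 5e-4)
  est <- bulk_nfr(a_t0, a_final, a_n2, pn, 1)$rate_raw
  mc_se <- sd(est) / sqrt(nrep)
  expect_lt(abs(mean(est) - true_rate), 3 * mc_se + 1e-9)
})

test_that("bulk_nfr_table appends rates to an incubation table", {
  inc <- tibble::tibble(
    cruise = "X", station = "1", depth_m = 2,
    a_pn_t0_pct = 0.3663, a_pn_final_pct = 0.5,
    a_enriched_pct = 24.7, v_enriched_l = 0.1, v_ambient_l = 1.1,
    pn_umol_l = 1, duration_d = 1, sd_ref_pct = 5e-4)
  out <- bulk_nfr_table(inc)
  expect_equal(out$a_n2_pct, mix_source_pool(24.7, 0.1, 1.1))
  expect_equal(round(out$rate_nmol_l_d, 2), 65.93)
  expect_error(bulk_nfr_table(inc[, -4]), "missing columns")
})
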