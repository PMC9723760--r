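# Single-cell and whole-symbiosis rates.

test_that("quota model is allometric in biovolume", {
  q <- quota_model()
  expect_gt(cell_n_quota(10, q), cell_n_quota(1, q))
  # linear when b = 1
  ql <- quota_model(b_exp = 1)
  expect_equal(cell_n_quota(20, ql), 2 * cell_n_quota(10, ql))
  # default calibration brackets the observed symbiosis quota ranges:
  # UCYN-A1 2.6-27.7, UCYN-A2 49.3-159.8 fmol N per cell
  expect_equal(cell_n_quota(c(0.956, 11.9)), c(2.6, 27.7),
               tolerance = 0.02)
  expect_equal(cell_n_quota(c(21.9, 77)), c(49.3, 159.8),
               tolerance = 0.02)
  expect_error(cell_n_quota(0), "biovolume")
  expect_error(cell_n_quota(-1), "biovolume")
})

test_that("single-cell mass balance matches the closed form", {
  expect_equal(single_cell_nfr(1.0, 0.3663, 5.0, 10, 1),
               (1 - 0.3663) / (5 - 0.3663) * 10)
  expect_equal(round(single_cell_nfr(1.0, 0.3663, 5.0, 10, 1), 4),
               1.3676)
  expect_equal(single_cell_nfr(0.3663, 0.3663, 5, 10, 1), 0)
  expect_equal(single_cell_nfr(5, 0.3663, 5, 10, 1), 10)
  # linear in quota and in the enrichment excess
  r1 <- single_cell_nfr(1.0, 0.3663, 5, 10, 1)
  expect_equal(single_cell_nfr(1.0, 0.3663, 5, 20, 1), 2 * r1)
  r2 <- single_cell_nfr(0.3663 + 2 * (1.0 - 0.3663), 0.3663, 5, 10, 1)
  expect_equal(r2, 2 * r1)
  expect_error(single_cell_nfr(1, 5, 5, 10, 1), "undefined")
})

test_that("symbiosis rate is the sum over partners with BDL as zero", {
  expect_equal(symbiosis_nfr(0, 0)$rate, 0)
  expect_equal(symbiosis_nfr(1.2, 0.3)$rate, 1.5)
  expect_equal(symbiosis_nfr(0.3, 1.2)$rate,
               symbiosis_nfr(1.2, 0.3)$rate)
  one_bdl <- symbiosis_nfr(1.2, 99, host_bdl = TRUE)
  expect_equal(one_bdl$rate, 1.2)
  expect_equal(one_bdl$status, "quantified")
  both <- symbiosis_nfr(5, 5, TRUE, TRUE)
  expect_equal(both$rate, 0)
  expect_equal(both$status, "BDL")
})

test_that("dilution correction is exactly 4x at the default", {
  expect_equal(dilution_correct(3.6), 14.4)
  expect_equal(dilution_correct(279.9), 1119.6)
  expect_equal(dilution_correct(7, dilution_fraction = 0), 7)
  # invertible
  set.seed(3)
  x <- runif(20, 0, 300)
  expect_equal(dilution_correct(x) * (1 - 0.75), x)
  expect_error(dilution_correct(1, dilution_fraction = 1), "dilution")
})

test_that("station aggregation gives sample SD and honours BDL policy", {
  a <- aggregate_symbiosis_rates(c(10, 20, 30))
  expect_equal(a$mean_rate, 20)
  expect_equal(a$sd, 10)
  expect_equal(a$n_cells, 3L)
  expect_equal(a$max_rate, 80)

  same <- aggregate_symbiosis_rates(rep(5.7, 4))
  expect_equal(same$mean_rate, 5.7)
  expect_equal(same$sd, 0)

  single <- aggregate_symbiosis_rates(7.7)
  expect_equal(single$sd, 0)
  expect_equal(single$n_cells, 1L)

  z <- aggregate_symbiosis_rates(c(10, 20, 99), bdl = c(F, F, T),
                                 bdl_policy = "zero")
  expect_equal(z$mean_rate, 10)
  ex <- aggregate_symbiosis_rates(c(10, 20, 99), bdl = c(F, F, T),
                                  bdl_policy = "exclude")
  expect_equal(ex$mean_rate, 15)
  expect_equal(ex$n_cells, 2L)
  expect_error(aggregate_symbiosis_rates(numeric(0)), "at least one")
})

test_that("rate estimates from counting noise converge to truth", {
  # bias at 1e5 counts per ROI below 1% over >= 500 replicates
  set.seed(71)
  a_n2 <- 2.3941
  quota <- 15
  true_rate <- 6.6
  a_true <- 0.3663 + true_rate * (a_n2 - 0.3663) / quota
  rois <- generate_nanosims_rois(a_true, 1e5, 600)
  est <- single_cell_nfr(rois$a_pct, 0.3663, a_n2, quota, 1)
  expect_lt(abs(mean(est) - true_rate) / true_rate, 0.01)
  # and tighter still at higher counts
  rois6 <- generate_nanosims_rois(a_true, 1e7, 600)
  est6 <- single_cell_nfr(rois6$a_pct, 0.3663, a_n2, quota, 1)
  expect_lt(sd(est6), sd(est))
})

test_that("symbiosis_rate_table aggregates a noiseless ROI table", {
  rois <- tibble::tibble(
    cruise = "X", station = "1", group = "UCYN-A1",
    association_id = rep(c("a1", "a2", "ref"), each = 2),
    partner = rep(c("symbiont", "host"), 3),
    a_final_pct = c(1.0, 0.8, 1.2, 1.0, 0.3663, 0.3663),
    biovolume_um3 = c(1, 6, 1, 6, 1, 6),
    is_reference = rep(c(FALSE, FALSE, TRUE), each = 2),
    a_n2_pct = 2.3941, duration_d = 1)
  out <- symbiosis_rate_table(rois)
  expect_equal(nrow(out), 1)
  expect_equal(out$n_cells, 2L)
  q1 <- cell_n_quota(1)
  q6 <- cell_n_quota(6)
  r_a1 <- single_cell_nfr(1.0, 0.3663, 2.3941, q1, 1) +
    single_cell_nfr(0.8, 0.3663, 2.3941, q6, 1)
  r_a2 <- single_cell_nfr(1.2, 0.3663, 2.3941, q1, 1) +
    single_cell_nfr(1.0, 0.3663, 2.3941, q6, 1)
  expect_equal(out$mean_rate, mean(c(r_a1, r_a2)))
  expect_equal(out$max_rate, 4 * out$mean_rate)
})
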