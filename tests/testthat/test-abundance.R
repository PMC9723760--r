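# qPCR censoring, copy-to-cell conversion and the contribution engine.

test_that("qPCR censoring classifies against LOD/LOQ with boundaries", {
  expect_equal(censor_qpcr(c(10, 100, 500), 25, 200),
               c("BDL", "DNQ", "quantified"))
  expect_equal(censor_qpcr(25, 25, 200), "BDL")       # copies = lod
  expect_equal(censor_qpcr(200, 25, 200), "quantified") # copies = loq
  expect_error(censor_qpcr(-1, 25, 200), "non-negative")
  expect_error(censor_qpcr(10, 200, 25), "LOD")
})

test_that("nifH copies convert to cells under the group convention", {
  expect_equal(cells_from_nifh(9.3e4, "UCYN-A2"), 9.3e3)
  expect_equal(cells_from_nifh(4.1e4, "UCYN-A1"), 4.1e4)
  expect_equal(cells_from_nifh(0, "UCYN-A1"), 0)
  # round trip with the convention
  conv <- copy_number_convention()
  set.seed(4)
  cells <- runif(6, 0, 1e6)
  g <- names(conv)
  expect_equal(cells_from_nifh(cells * conv[g], g, conv), cells)
  # overrides
  conv2 <- copy_number_convention("UCYN-A2" = 5)
  expect_equal(cells_from_nifh(100, "UCYN-A2", conv2), 20)
  expect_error(copy_number_convention("UCYN-A2" = 0.5), "integers")
  expect_error(cells_from_nifh(10, "nope"), "unknown group")
})

test_that("volumetric scaling and contribution match the survey rows", {
  expect_equal(round(volumetric_group_nfr(3.6, 4.1e4), 2), 0.15)
  expect_equal(round(volumetric_group_nfr(5.7, 8.8e5), 1), 5.0)
  expect_equal(volumetric_group_nfr(5, 0), 0)

  expect_equal(round(contribution_percent(0.1476, 2.3)), 6)
  expect_equal(round(contribution_percent(5.016, 3.4)), 148)
  expect_equal(contribution_percent(2.2, 2.2), 100)
  # BDL bulk falls back to the LOD
  expect_equal(contribution_percent(0.7936, NA, bulk_lod = 0.8), 99.2)
  expect_error(contribution_percent(1, 0), "LOD")
})

test_that("first-order SD propagation follows the quadrature rule", {
  expect_equal(propagate_sd_product_quotient(c(10, 5), c(1, 0.5), 50),
               50 * sqrt(0.01 + 0.01))
  expect_equal(round(propagate_sd_product_quotient(c(10, 5), c(1, 0.5),
                                                   50), 2), 7.07)
  expect_equal(round(propagate_sd_product_quotient(c(10, 5), c(1, 0.5),
                                                   2), 3), 0.283)
  # a term with zero SD contributes nothing
  expect_equal(propagate_sd_product_quotient(c(10, 5), c(1, 0), 50),
               propagate_sd_product_quotient(c(10, 99), c(1, 0), 50))
  expect_error(propagate_sd_product_quotient(c(0, 5), c(1, 1), 1),
               "undefined")
})

test_that("contribution engine reproduces the published survey rows", {
  ct <- sccs_contributions()
  expect_equal(nrow(ct), 6)
  key <- paste(ct$cruise, ct$station, ct$group)

  row <- function(k) ct[key == k, ]
  r1 <- row("SP1714 1 UCYN-A1")
  expect_equal(round(r1$volumetric_nfr, 2), 0.15)
  expect_equal(round(r1$contribution_pct), 6)
  expect_equal(r1$max_single_cell_nfr, 14.4)
  expect_equal(round(r1$max_volumetric_nfr, 1), 0.6)
  expect_equal(round(r1$max_contribution_pct), 26)

  r5 <- row("SP1727 5 UCYN-A1")
  expect_true(r5$bulk_is_lod)
  expect_equal(round(r5$volumetric_nfr, 1), 0.8)
  expect_equal(round(r5$contribution_pct), 99)
  expect_equal(r5$max_single_cell_nfr, 51.2)

  # the corrected contribution is exactly 4x the uncorrected one
  expect_equal(ct$max_contribution_pct, 4 * ct$contribution_pct)
  expect_equal(ct$max_volumetric_nfr, 4 * ct$volumetric_nfr)
})

test_that("DNQ policy excludes or imputes at half the LOQ", {
  rates <- tibble::tibble(cruise = "X", station = "1",
                          group = "UCYN-A1", n_cells = 3L,
                          mean_rate = 10, sd = 1)
  qpcr <- tibble::tibble(cruise = "X", station = "1",
                         group = "UCYN-A1", copies_per_l = 100,
                         sd = 10, lod = 25, loq = 200)
  bulk <- tibble::tibble(cruise = "X", station = "1",
                         rate_nmol_l_d = 5, sd = 0.5, lod = 0.3,
                         status = "quantified")
  excl <- group_contributions(rates, qpcr, bulk)
  expect_equal(nrow(excl), 0)
  imp <- group_contributions(rates, qpcr, bulk, dnq_policy = "loq_half")
  expect_equal(imp$cells_per_l, 100)
  expect_equal(imp$qpcr_status, "DNQ")
})
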