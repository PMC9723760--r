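# Published spot values from a Southern California Current System
# UCYN-A survey (May and October 2017 cruises), transcribed as packaged
# example data. These are the measured inputs of the contribution
# calculation — per-cell rates, nifH abundances and community rates —
# and a few hydrochemistry rows; everything downstream (volumetric
# rates, contributions, corrected maxima, P*) is recomputed by the
# package.

#' Measured inputs for UCYN-A contribution estimates (SCCS survey)
#'
#' One row per cruise x station x UCYN-A sublineage: the measured mean
#' single-cell N2-fixation rate (with SD and number of associations),
#' the qPCR nifH abundance (with SD), and the bulk community rate (with
#' SD and detection limit). `bulk_status` records stations where the
#' community rate was below detection and its LOD stands in as the
#' denominator. Assay limits are the survey-wide nifH LOD/LOQ
#' (25-31 / 200-250 copies/l; the midpoints are carried here).
#'
#' @return A 6-row tibble.
#' @export
#' @examples
#' sccs_ucyna_survey()
sccs_ucyna_survey <- function() {
  tibble::tribble(
    ~cruise, ~station, ~group, ~n_cells,
    ~single_cell_nfr, ~single_cell_sd,
    ~nifh_copies_l, ~nifh_sd, ~bulk_nfr, ~bulk_sd, ~bulk_lod,
    ~bulk_status,
    "SP1714", "1", "UCYN-A1", 10L, 3.6, 2.2,
    4.1e4, 7.3e2, 2.3, 1.3, 0.4, "quantified",
    "SP1727", "1", "UCYN-A2", 6L, 125.8, 41.6,
    9.3e4, 4.2e3, 2.2, 0.2, 0.7, "quantified",
    "SP1727", "5", "UCYN-A1", 6L, 12.8, 13.5,
    6.2e4, 1.5e3, NA, NA, 0.8, "BDL",
    "SP1727", "7", "UCYN-A2", 6L, 279.9, 53.7,
    1.2e5, 2.9e3, 6.7, 0.8, 5.4, "quantified",
    "SP1727", "14", "UCYN-A1", 10L, 5.7, 5.4,
    8.8e5, 8.1e4, 3.4, 0.2, 1.1, "quantified",
    "SP1727", "14", "UCYN-A2", 5L, 27.0, 15.4,
    2.9e4, 1.1e2, 3.4, 0.2, 1.1, "quantified"
  )
}

#' Hydrochemistry spot rows from the SCCS survey
#'
#' A few station/depth rows with nitrate+nitrite, phosphate and Chl a,
#' for exercising [p_star()] and censoring against published values.
#' `p_star_printed` is the rounded value as published. Two rows are
#' retained although their published P* is not consistent with their own
#' published nutrients (station 7 at 32 m: 0.75 - 12.73/16 rounds to
#' -0.05, printed -0.04; station 1 at 2 m: 0.09 - 0.05/16 rounds to
#' 0.09, printed 0.08); `printed_consistent = FALSE` excludes them from
#' reproduction checks.
#'
#' @return A tibble with one row per spot sample.
#' @export
sccs_hydro_spots <- function() {
  tibble::tribble(
    ~cruise, ~station, ~depth_m, ~temp_c, ~salinity,
    ~no3no2_umol_l, ~po4_umol_l, ~chl_ug_l, ~p_star_printed,
    ~printed_consistent,
    "SP1714", "1", 2, 18.22, 33.40, 0.05, 0.09, 0.173, 0.08, FALSE,
    "SP1714", "1", 30, 11.91, 33.41, 9.82, 0.88, 0.900, 0.27, TRUE,
    "SP1714", "2", 29, 13.63, 33.27, 9.05, 0.64, 0.950, 0.07, TRUE,
    "SP1714", "5", 2, 14.54, 33.23, 0.12, 0.10, 0.307, 0.09, TRUE,
    "SP1714", "7", 32, 12.15, 33.37, 12.73, 0.75, 0.275, -0.04, FALSE,
    "SP1727", "2", 2, 20.46, 33.58, 0.00, 0.03, 0.115, 0.03, TRUE
  )
}

#' Contribution table recomputed from the survey's measured inputs
#'
#' Feeds [sccs_ucyna_survey()] through [group_contributions()] under the
#' survey conventions (1 nifH copy per UCYN-A1 cell, 10 per UCYN-A2
#' cell, 75% isotope dilution).
#'
#' @inheritParams group_contributions
#' @return The [group_contributions()] tibble for the six published rows.
#' @export
#' @examples
#' sccs_contributions()[, c("station", "group", "volumetric_nfr",
#'                          "contribution_pct")]
sccs_contributions <- function(convention = copy_number_convention(),
                               dilution_fraction = 0.75) {
  sv <- sccs_ucyna_survey()
  rates <- sv |>
    dplyr::transmute(.data$cruise, .data$station, .data$group,
                     n_cells = .data$n_cells,
                     mean_rate = .data$single_cell_nfr,
                     sd = .data$single_cell_sd)
  # abundances are already quantified (well above the assay LOQ)
  qpcr <- sv |>
    dplyr::transmute(.data$cruise, .data$station, .data$group,
                     copies_per_l = .data$nifh_copies_l,
                     sd = .data$nifh_sd, lod = 28, loq = 225)
  bulk <- sv |>
    dplyr::transmute(.data$cruise, .data$station,
                     rate_nmol_l_d = .data$bulk_nfr, sd = .data$bulk_sd,
                     lod = .data$bulk_lod, status = .data$bulk_status) |>
    dplyr::distinct()
  group_contributions(rates, qpcr, bulk, convention = convention,
                      dilution_fraction = dilution_fraction)
}
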