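# Single-cell and whole-symbiosis N2-fixation rates from nanoSIMS atom%
# and biovolume-derived cell N quotas.

#' Default biovolume-to-quota model
#'
#' Carbon per cell follows the allometric scaling
#' `pg C = a_coeff * V^b_exp` (V in um^3) and is converted to nitrogen with
#' a molar C:N ratio. The defaults use the protist carbon scaling
#' a = 0.216 pg C um^-3, b = 0.939 (Menden-Deuer & Lessard type) with
#' Redfield C:N = 106/16; they are a surrogate calibration chosen so that
#' symbiosis N quotas fall in the ranges observed for UCYN-A1 (roughly
#' 2.6-27.7 fmol N per cell) and UCYN-A2 (49.3-159.8 fmol N per cell)
#' symbioses at realistic partner biovolumes.
#'
#' @param a_coeff Carbon scaling coefficient (pg C um^-3b), > 0.
#' @param b_exp Dimensionless allometric exponent.
#' @param c_to_n Molar C:N ratio, > 0.
#' @return A list of class `quota_model`.
#' @export
quota_model <- function(a_coeff = 0.216, b_exp = 0.939, c_to_n = 106 / 16) {
  stopifnot(a_coeff > 0, c_to_n > 0)
  structure(list(a_coeff = a_coeff, b_exp = b_exp, c_to_n = c_to_n),
            class = "quota_model")
}

#' Cell nitrogen quota from biovolume
#'
#' @param biovolume_um3 Cell biovolume (um^3), > 0.
#' @param q A [quota_model()].
#' @return Cell N quota, fmol N per cell (pg C / 12.011 = pmol C, x1000 =
#'   fmol C, / C:N = fmol N).
#' @export
#' @examples
#' cell_n_quota(10)
cell_n_quota <- function(biovolume_um3, q = quota_model()) {
  stopifnot(inherits(q, "quota_model"))
  if (any(biovolume_um3 <= 0, na.rm = TRUE)) {
    stop("biovolume must be positive", call. = FALSE)
  }
  pg_c <- q$a_coeff * biovolume_um3^q$b_exp
  fmol_c <- pg_c / 12.011 * 1000
  fmol_c / q$c_to_n
}

#' Single-cell N2-fixation rate from nanoSIMS atom percent
#'
#' Same isotope mass balance as the bulk rate, applied to one cell's
#' nitrogen quota:
#' rate = (a_final - a_t0) / (a_n2 - a_t0) * quota / duration.
#'
#' @param a_final Atom% 15N of the enriched cell.
#' @param a_t0 Atom% 15N of unenriched reference cells of the same partner
#'   type (typically their mean).
#' @param a_n2 Atom% 15N of the dissolved-N2 source pool; must exceed
#'   `a_t0`.
#' @param quota_fmol Cell N quota (fmol N), > 0.
#' @param duration_d Incubation duration (d), > 0.
#' @return Rate in fmol N per cell per day. Zero at zero enrichment;
#'   `quota_fmol / duration_d` at full labelling.
#' @export
#' @examples
#' single_cell_nfr(1.0, 0.3663, 5.0, quota_fmol = 10, duration_d = 1)
single_cell_nfr <- function(a_final, a_t0, a_n2, quota_fmol, duration_d) {
  if (any(a_n2 <= a_t0, na.rm = TRUE)) {
    stop("source-pool atom% must exceed t0 atom%: rate undefined",
         call. = FALSE)
  }
  if (any(duration_d <= 0, na.rm = TRUE)) {
    stop("incubation duration must be positive", call. = FALSE)
  }
  if (any(quota_fmol <= 0, na.rm = TRUE)) {
    stop("cell N quota must be positive", call. = FALSE)
  }
  (a_final - a_t0) / (a_n2 - a_t0) * quota_fmol / duration_d
}

#' Whole-symbiosis rate from its two partners
#'
#' Symbiont and host rates are computed independently from their own
#' biovolumes and atom% values, then summed to give one rate for the
#' intact symbiosis. A partner below detection contributes zero and the
#' BDL flag is propagated.
#'
#' @param symbiont_rate,host_rate Per-cell rates (fmol N/cell/d) for the
#'   two partners of one association.
#' @param symbiont_bdl,host_bdl Logical; partner below its single-cell
#'   detection limit (its rate enters as 0).
#' @return A tibble with `rate` (fmol N/cell/d) and `status`
#'   (`"quantified"` unless both partners are BDL, then `"BDL"`).
#' @export
symbiosis_nfr <- function(symbiont_rate, host_rate,
                          symbiont_bdl = FALSE, host_bdl = FALSE) {
  s <- ifelse(symbiont_bdl, 0, symbiont_rate)
  h <- ifelse(host_bdl, 0, host_rate)
  tibble::tibble(
    rate = s + h,
    status = ifelse(symbiont_bdl & host_bdl, "BDL", "quantified")
  )
}

#' Isotope-dilution correction for single-cell rates
#'
#' Sample fixation and processing dilute the 15N label; with a dilution
#' fraction d the measured rate underestimates the true rate by the factor
#' (1 - d), so the corrected ("maximum") rate is rate / (1 - d). At the
#' default d = 0.75 the correction is exactly 4x.
#'
#' @param rate Measured rate (any rate unit).
#' @param dilution_fraction Fraction of label lost during processing, in
#'   `[0, 1)`. Default 0.75.
#' @return Dilution-corrected rate, same unit as `rate`.
#' @export
#' @examples
#' dilution_correct(3.6)    # 14.4
#' dilution_correct(279.9)  # 1119.6
dilution_correct <- function(rate, dilution_fraction = 0.75) {
  if (any(dilution_fraction < 0 | dilution_fraction >= 1, na.rm = TRUE)) {
    stop("dilution_fraction must be in [0, 1)", call. = FALSE)
  }
  rate / (1 - dilution_fraction)
}

#' Aggregate per-association symbiosis rates for one station and group
#'
#' @param rates Numeric vector of per-association rates (fmol N/cell/d).
#' @param bdl Logical vector marking associations below detection.
#' @param bdl_policy How BDL associations enter the mean: `"zero"`
#'   (default; counted as 0, as for conservative station means) or
#'   `"exclude"` (dropped from mean, SD and n).
#' @param dilution_fraction Passed to [dilution_correct()] for the
#'   corrected maximum.
#' @return A one-row tibble: `mean_rate`, `sd` (sample SD; 0 for a single
#'   association), `n_cells`, `max_rate`, `status`.
#' @export
#' @examples
#' aggregate_symbiosis_rates(c(10, 20, 30))
aggregate_symbiosis_rates <- function(rates, bdl = rep(FALSE, length(rates)),
                                      bdl_policy = c("zero", "exclude"),
                                      dilution_fraction = 0.75) {
  bdl_policy <- match.arg(bdl_policy)
  if (length(rates) == 0) {
    stop("at least one association is required", call. = FALSE)
  }
  stopifnot(length(bdl) == length(rates))
  x <- rates
  if (bdl_policy == "zero") {
    x[bdl] <- 0
  } else {
    x <- x[!bdl]
    if (length(x) == 0) {
      return(tibble::tibble(mean_rate = NA_real_, sd = NA_real_,
                            n_cells = 0L, max_rate = NA_real_,
                            status = "BDL"))
    }
  }
  m <- mean(x)
  s <- if (length(x) > 1) stats::sd(x) else 0
  tibble::tibble(
    mean_rate = m,
    sd = s,
    n_cells = length(x),
    max_rate = dilution_correct(m, dilution_fraction),
    status = if (all(bdl)) "BDL" else "quantified"
  )
}

#' Single-cell rates and station summaries from a table of nanoSIMS ROIs
#'
#' Takes the `nanosims_rois` table (one row per region of interest), uses
#' the unenriched reference cells (`is_reference`) of each cruise x station
#' x partner stratum to set the t0 atom% and the single-cell detection
#' limit (mean + `k_lod` * SD of reference atom%), computes per-partner
#' rates from biovolume-derived quotas, sums partners within each
#' association and aggregates per station and group.
#'
#' @param rois Data frame with columns `cruise`, `station`, `group`,
#'   `association_id`, `partner` (`"symbiont"`/`"host"`), `a_final_pct`
#'   (or `r15_14`, converted), `biovolume_um3`, `is_reference` (logical),
#'   `a_n2_pct`, `duration_d`.
#' @param q A [quota_model()].
#' @param k_lod Reference-cell SD multiplier for the single-cell detection
#'   limit.
#' @inheritParams aggregate_symbiosis_rates
#' @return A tibble `symbiosis_rates` with one row per cruise x station x
#'   group: `mean_rate`, `sd`, `n_cells`, `max_rate`, `status`.
#' @export
symbiosis_rate_table <- function(rois, q = quota_model(), k_lod = 3,
                                 bdl_policy = "zero",
                                 dilution_fraction = 0.75) {
  rois <- tibble::as_tibble(rois)
  if (!"a_final_pct" %in% names(rois)) {
    if (!"r15_14" %in% names(rois)) {
      stop("rois table needs a_final_pct or r15_14", call. = FALSE)
    }
    rois$a_final_pct <- atom_percent_from_ratio(rois$r15_14)
  }
  need <- c("cruise", "station", "group", "association_id", "partner",
            "biovolume_um3", "is_reference", "a_n2_pct", "duration_d")
  miss <- setdiff(need, names(rois))
  if (length(miss)) {
    stop("rois table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }

  refs <- rois |>
    dplyr::filter(.data$is_reference) |>
    dplyr::group_by(.data$cruise, .data$station, .data$group,
                    .data$partner) |>
    dplyr::summarise(
      a_t0_pct = mean(.data$a_final_pct),
      a_lod_pct = mean(.data$a_final_pct) +
        k_lod * ifelse(dplyr::n() > 1, stats::sd(.data$a_final_pct), 0),
      .groups = "drop"
    )

  cells <- rois |>
    dplyr::filter(!.data$is_reference) |>
    dplyr::inner_join(refs,
                      by = c("cruise", "station", "group", "partner")) |>
    dplyr::mutate(
      quota_fmol = cell_n_quota(.data$biovolume_um3, q),
      bdl = .data$a_final_pct <= .data$a_lod_pct,
      rate = ifelse(.data$bdl, 0,
                    single_cell_nfr(.data$a_final_pct, .data$a_t0_pct,
                                    .data$a_n2_pct, .data$quota_fmol,
                                    .data$duration_d))
    )

  assoc <- cells |>
    dplyr::group_by(.data$cruise, .data$station, .data$group,
                    .data$association_id) |>
    dplyr::summarise(rate = sum(.data$rate), bdl = all(.data$bdl),
                     .groups = "drop")

  assoc |>
    dplyr::group_by(.data$cruise, .data$station, .data$group) |>
    dplyr::reframe(aggregate_symbiosis_rates(
      .data$rate, .data$bdl, bdl_policy = bdl_policy,
      dilution_fraction = dilution_fraction))
}
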