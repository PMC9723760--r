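# qPCR censoring, nifH-copy to cell conversion, volumetric group rates,
# percent contribution to bulk N2 fixation, and first-order uncertainty
# propagation.

#' Three-way censoring of a qPCR measurement
#'
#' Targets with nifH copies above the limit of detection (LOD) but below
#' the limit of quantitation (LOQ) are "detected, not quantified" (DNQ);
#' at or below the LOD they are below detection (BDL). Boundary values:
#' `copies = lod` is BDL, `copies = loq` is quantified.
#'
#' @param copies_per_l nifH copies per litre, >= 0.
#' @param lod,loq Assay detection and quantitation limits (copies/l),
#'   `lod < loq`.
#' @return Character vector: `"BDL"`, `"DNQ"` or `"quantified"`.
#' @export
#' @examples
#' censor_qpcr(c(10, 100, 500), lod = 25, loq = 200)
censor_qpcr <- function(copies_per_l, lod, loq) {
  if (any(lod >= loq, na.rm = TRUE)) {
    stop("assay LOD must be below LOQ", call. = FALSE)
  }
  if (any(copies_per_l < 0, na.rm = TRUE)) {
    stop("copies must be non-negative", call. = FALSE)
  }
  dplyr::case_when(
    copies_per_l <= lod ~ "BDL",
    copies_per_l < loq ~ "DNQ",
    TRUE ~ "quantified"
  )
}

#' Per-group nifH copies-per-cell convention
#'
#' UCYN-A1 carries one nifH copy per symbiont cell; the UCYN-A2 assay is
#' conventionally scaled at 10 copies per cell (high end of the reported
#' polyploidy range, so cell abundances — and hence contributions — are
#' conservative). Other groups default to 1.
#'
#' @param ... Named overrides, e.g. `"UCYN-A2" = 6`.
#' @return Named numeric vector of copies per cell.
#' @export
copy_number_convention <- function(...) {
  conv <- c("UCYN-A1" = 1, "UCYN-A2" = 10, "UCYN-B" = 1,
            "Trichodesmium" = 1, "Het-2" = 1, "gammaA" = 1)
  over <- c(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over)))) {
      stop("overrides must be named", call. = FALSE)
    }
    if (any(over < 1) || any(over != round(over))) {
      stop("copies per cell must be integers >= 1", call. = FALSE)
    }
    conv[names(over)] <- over
  }
  conv
}

#' Convert nifH gene copies to cell abundance
#'
#' @param copies_per_l nifH copies per litre, >= 0.
#' @param group Diazotroph group name(s), matched against the convention.
#' @param convention Named copies-per-cell vector from
#'   [copy_number_convention()].
#' @return Cells per litre (`copies / copies_per_cell`).
#' @export
#' @examples
#' cells_from_nifh(9.3e4, "UCYN-A2") # 9300
cells_from_nifh <- function(copies_per_l, group,
                            convention = copy_number_convention()) {
  if (any(copies_per_l < 0, na.rm = TRUE)) {
    stop("copies must be non-negative", call. = FALSE)
  }
  cpc <- convention[group]
  if (any(is.na(cpc))) {
    stop("unknown group(s): ",
         paste(unique(group[is.na(cpc)]), collapse = ", "), call. = FALSE)
  }
  unname(copies_per_l / cpc)
}

#' Volumetric group N2-fixation rate
#'
#' @param single_cell_rate Per-cell rate (fmol N/cell/d), >= 0.
#' @param cells_per_l Cell abundance (cells/l), >= 0.
#' @return Volumetric rate, nmol N/l/d (fmol x cells x 1e-6).
#' @export
#' @examples
#' volumetric_group_nfr(3.6, 4.1e4) # 0.1476
volumetric_group_nfr <- function(single_cell_rate, cells_per_l) {
  if (any(single_cell_rate < 0, na.rm = TRUE) ||
      any(cells_per_l < 0, na.rm = TRUE)) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  single_cell_rate * cells_per_l * 1e-6
}

#' Percent contribution of a group to the bulk community rate
#'
#' When the bulk rate is below detection, the bulk LOD is used as the
#' denominator (the contribution is then a lower bound relative to the
#' detectable rate) and should be flagged by the caller. Contributions may
#' exceed 100%.
#'
#' @param group_rate Group volumetric rate (nmol N/l/d).
#' @param bulk_rate Bulk community rate (nmol N/l/d); if not positive and
#'   `bulk_lod` is supplied, the LOD is used instead.
#' @param bulk_lod Optional bulk LOD (nmol N/l/d) for BDL bulk rates.
#' @return Contribution in percent.
#' @export
#' @examples
#' contribution_percent(0.1476, 2.3) # ~6.4
contribution_percent <- function(group_rate, bulk_rate, bulk_lod = NULL) {
  denom <- bulk_rate
  if (!is.null(bulk_lod)) {
    denom <- ifelse(is.na(denom) | denom <= 0, bulk_lod, denom)
  }
  if (any(is.na(denom)) || any(denom <= 0)) {
    stop("bulk rate is not positive and no LOD is available",
         call. = FALSE)
  }
  100 * group_rate / denom
}

#' First-order SD propagation through products and quotients
#'
#' For a product or quotient of independent terms, the relative SD of the
#' result is the quadrature sum of the terms' relative SDs:
#' `sd_out / |out| = sqrt(sum((sd_i / value_i)^2))`.
#'
#' @param values Numeric vector of term values (nonzero where the SD is
#'   nonzero).
#' @param sds Their standard deviations, >= 0.
#' @param out Value of the product/quotient the SD is propagated to.
#' @return Absolute SD of `out`.
#' @export
#' @examples
#' propagate_sd_product_quotient(c(10, 5), c(1, 0.5), out = 50)  # 7.07
#' propagate_sd_product_quotient(c(10, 5), c(1, 0.5), out = 2)   # 0.283
propagate_sd_product_quotient <- function(values, sds, out) {
  stopifnot(length(values) == length(sds))
  if (any(sds < 0, na.rm = TRUE)) {
    stop("SDs must be non-negative", call. = FALSE)
  }
  if (any(values == 0 & sds > 0, na.rm = TRUE)) {
    stop("zero value with nonzero SD: relative SD undefined",
         call. = FALSE)
  }
  rel <- ifelse(sds == 0, 0, sds / abs(values))
  abs(out) * sqrt(sum(rel^2))
}

#' Group contributions to bulk N2 fixation (the scaling engine)
#'
#' Joins per-station symbiosis rates with qPCR abundances and bulk rates,
#' converts copies to cells under the copy-number convention, and reports
#' volumetric rates, percent contributions and their dilution-corrected
#' maxima with first-order propagated SDs.
#'
#' @param rates Data frame with columns `cruise`, `station`, `group`,
#'   `mean_rate`, `sd` (fmol N/cell/d; e.g. from [symbiosis_rate_table()]).
#' @param qpcr Data frame with columns `cruise`, `station`, `group`,
#'   `copies_per_l`, `sd`, `lod`, `loq` (copies/l).
#' @param bulk Data frame with columns `cruise`, `station`,
#'   `rate_nmol_l_d`, `sd` (may be NA), `lod`, `status`.
#' @param convention Copies-per-cell from [copy_number_convention()].
#' @param dilution_fraction Isotope-dilution fraction (default 0.75).
#' @param dnq_policy DNQ qPCR handling: `"exclude"` (default; dropped with
#'   a flag) or `"loq_half"` (imputed at LOQ/2, flagged).
#' @return Tibble with one row per cruise x station x group:
#'   `cells_per_l`, `volumetric_nfr`, `volumetric_nfr_sd`,
#'   `contribution_pct`, `contribution_pct_sd`, `max_single_cell_nfr`,
#'   `max_volumetric_nfr`, `max_contribution_pct`, `qpcr_status`,
#'   `bulk_status`, `bulk_is_lod`.
#' @export
group_contributions <- function(rates, qpcr, bulk,
                                convention = copy_number_convention(),
                                dilution_fraction = 0.75,
                                dnq_policy = c("exclude", "loq_half")) {
  dnq_policy <- match.arg(dnq_policy)
  qp <- tibble::as_tibble(qpcr) |>
    dplyr::mutate(qpcr_status = censor_qpcr(.data$copies_per_l, .data$lod,
                                            .data$loq))
  if (dnq_policy == "exclude") {
    qp <- dplyr::filter(qp, .data$qpcr_status == "quantified")
  } else {
    qp <- qp |>
      dplyr::filter(.data$qpcr_status != "BDL") |>
      dplyr::mutate(copies_per_l = ifelse(.data$qpcr_status == "DNQ",
                                          .data$loq / 2,
                                          .data$copies_per_l))
  }

  bk <- tibble::as_tibble(bulk) |>
    dplyr::transmute(.data$cruise, .data$station,
                     bulk_rate = .data$rate_nmol_l_d,
                     bulk_sd = .data$sd, bulk_lod = .data$lod,
                     bulk_status = .data$status)

  tibble::as_tibble(rates) |>
    dplyr::inner_join(qp, by = c("cruise", "station", "group"),
                      suffix = c("_rate", "_qpcr")) |>
    dplyr::inner_join(bk, by = c("cruise", "station")) |>
    dplyr::mutate(
      cells_per_l = cells_from_nifh(.data$copies_per_l, .data$group,
                                    convention),
      cells_sd = cells_from_nifh(.data$sd_qpcr, .data$group, convention),
      volumetric_nfr = volumetric_group_nfr(.data$mean_rate,
                                            .data$cells_per_l),
      bulk_is_lod = is.na(.data$bulk_rate) | .data$bulk_rate <= 0 |
        .data$bulk_status == "BDL",
      bulk_denom = ifelse(.data$bulk_is_lod, .data$bulk_lod,
                          .data$bulk_rate),
      contribution_pct = contribution_percent(.data$volumetric_nfr,
                                              .data$bulk_denom,
                                              bulk_lod = .data$bulk_lod),
      max_single_cell_nfr = dilution_correct(.data$mean_rate,
                                             dilution_fraction),
      max_volumetric_nfr = dilution_correct(.data$volumetric_nfr,
                                            dilution_fraction),
      max_contribution_pct = dilution_correct(.data$contribution_pct,
                                              dilution_fraction)
    ) |>
    dplyr::mutate(
      # exact first-order product/quotient rules, safe at zero rates
      volumetric_nfr_sd = 1e-6 * sqrt(
        (.data$cells_per_l * .data$sd_rate)^2 +
          (.data$mean_rate * .data$cells_sd)^2),
      bulk_denom_sd = ifelse(.data$bulk_is_lod | is.na(.data$bulk_sd), 0,
                             .data$bulk_sd),
      contribution_pct_sd = 100 * sqrt(
        (.data$volumetric_nfr_sd / .data$bulk_denom)^2 +
          (.data$volumetric_nfr * .data$bulk_denom_sd /
             .data$bulk_denom^2)^2)
    ) |>
    dplyr::select(dplyr::any_of(c(
      "cruise", "station", "group", "n_cells", "mean_rate", "sd_rate",
      "copies_per_l", "qpcr_status", "cells_per_l", "bulk_rate",
      "bulk_status", "bulk_is_lod", "volumetric_nfr", "volumetric_nfr_sd",
      "contribution_pct", "contribution_pct_sd", "max_single_cell_nfr",
      "max_volumetric_nfr", "max_contribution_pct")))
}
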