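# Isotope bookkeeping and bulk-community N2-fixation rates from 15N2
# tracer incubations, including detection limits (LOD) and minimum
# quantifiable rates (MQR).

#' Convert a heavy/light isotope ratio to atom percent
#'
#' The ratio r = 15N/14N measured from ion counts maps to
#' atom% = 100 r / (1 + r), the percentage of all N atoms that are 15N.
#'
#' @param r Numeric vector of 15N/14N ratios, each >= 0.
#' @return Atom percent 15N, in `[0, 100)`.
#' @export
#' @examples
#' atom_percent_from_ratio(0.0036765) # natural abundance, ~0.3663
atom_percent_from_ratio <- function(r) {
  stopifnot(is.numeric(r))
  if (any(r < 0, na.rm = TRUE)) {
    stop("isotope ratio must be >= 0", call. = FALSE)
  }
  100 * r / (1 + r)
}

#' Inverse of [atom_percent_from_ratio()]
#'
#' @param atom_pct Atom percent 15N, in `[0, 100)`.
#' @return 15N/14N ratio.
#' @export
ratio_from_atom_percent <- function(atom_pct) {
  stopifnot(is.numeric(atom_pct))
  if (any(atom_pct < 0 | atom_pct >= 100, na.rm = TRUE)) {
    stop("atom percent must be in [0, 100)", call. = FALSE)
  }
  f <- atom_pct / 100
  f / (1 - f)
}

#' Atom percent 15N of the dissolved-N2 source pool after tracer addition
#'
#' Volume-weighted mixing of 15N2-enriched seawater into the incubation
#' bottle, assuming equal dissolved-N2 concentration per litre in the
#' enriched and ambient water (no solubility correction).
#'
#' @param a_enriched Atom% 15N of the enriched seawater.
#' @param v_enriched Volume of enriched seawater added (l), >= 0.
#' @param v_ambient Ambient seawater volume (l), > 0.
#' @param a_ambient Atom% 15N of ambient dissolved N2; defaults to natural
#'   abundance (0.3663).
#' @return Source-pool atom% 15N, between `a_ambient` and `a_enriched`.
#' @export
#' @examples
#' mix_source_pool(24.7, 0.1, 1.1) # ~2.394
mix_source_pool <- function(a_enriched, v_enriched, v_ambient,
                            a_ambient = NAT_ABUNDANCE_15N) {
  stopifnot(is.numeric(a_enriched), is.numeric(v_enriched),
            is.numeric(v_ambient), is.numeric(a_ambient))
  if (any(v_enriched < 0, na.rm = TRUE) || any(v_ambient < 0, na.rm = TRUE)) {
    stop("volumes must be non-negative", call. = FALSE)
  }
  tot <- v_enriched + v_ambient
  if (any(tot <= 0, na.rm = TRUE)) {
    stop("total incubation volume must be positive", call. = FALSE)
  }
  bad <- function(a) any(a < 0 | a > 100, na.rm = TRUE)
  if (bad(a_enriched) || bad(a_ambient)) {
    stop("atom percent values must lie in [0, 100]", call. = FALSE)
  }
  (v_enriched * a_enriched + v_ambient * a_ambient) / tot
}

#' Bulk-community N2-fixation rate from a 15N2 incubation
#'
#' Isotope mass balance on particulate nitrogen (PN):
#' \deqn{NFR = \frac{A_{PN}^{final} - A_{PN}^{t0}}{A_{N2} - A_{PN}^{t0}}
#'   \cdot \frac{[PN]}{\Delta t}}
#' with atom% values in percent, `[PN]` in umol N/l and the returned rate
#' in nmol N/l/d. The status is set against the detection limit (LOD) and
#' minimum quantifiable rate (MQR) computed by [nfr_detection_limits()]:
#' `quantified` at or above the MQR, `DNQ` (detected, not quantified)
#' between LOD and MQR, `BDL` below the LOD. Negative enrichment
#' (`a_pn_final < a_pn_t0`) is reported as BDL with rate 0; the raw signed
#' rate is retained in `rate_raw` for diagnostics.
#'
#' @param a_pn_t0,a_pn_final Atom% 15N of PN at the start and end of the
#'   incubation.
#' @param a_n2 Atom% 15N of the dissolved-N2 source pool (see
#'   [mix_source_pool()]); must exceed `a_pn_t0`.
#' @param pn_umol_l PN concentration (umol N/l), > 0.
#' @param duration_d Incubation duration (d), > 0.
#' @param sd_a_pn_ref SD of replicate reference (t0) atom% measurements,
#'   used for LOD/MQR; 0 disables censoring.
#' @param k_lod,k_mqr LOD and MQR multipliers on `sd_a_pn_ref`
#'   (conventionally 3 and 10).
#' @return A tibble with columns `rate_nmol_l_d`, `rate_raw`, `lod`, `mqr`
#'   (all nmol N/l/d) and `status`.
#' @export
#' @examples
#' bulk_nfr(0.3663, 0.5, 2.3941, pn_umol_l = 1, duration_d = 1)
bulk_nfr <- function(a_pn_t0, a_pn_final, a_n2, pn_umol_l, duration_d,
                     sd_a_pn_ref = 0, k_lod = 3, k_mqr = 10) {
  stopifnot(k_mqr >= k_lod, k_lod > 0)
  if (any(duration_d <= 0, na.rm = TRUE)) {
    stop("incubation duration must be positive", call. = FALSE)
  }
  if (any(pn_umol_l <= 0, na.rm = TRUE)) {
    stop("PN concentration must be positive", call. = FALSE)
  }
  if (any(a_n2 <= a_pn_t0, na.rm = TRUE)) {
    stop("source-pool atom% must exceed t0 atom%: rate undefined",
         call. = FALSE)
  }
  if (any(sd_a_pn_ref < 0, na.rm = TRUE)) {
    stop("sd_a_pn_ref must be >= 0", call. = FALSE)
  }
  # umol/l -> nmol/l: x1000
  raw <- (a_pn_final - a_pn_t0) / (a_n2 - a_pn_t0) *
    pn_umol_l * 1000 / duration_d
  lims <- nfr_detection_limits(a_pn_t0, a_n2, pn_umol_l, duration_d,
                               sd_a_pn_ref, k_lod = k_lod, k_mqr = k_mqr)
  status <- dplyr::case_when(
    raw <= 0 ~ "BDL",
    raw < lims$lod ~ "BDL",
    raw < lims$mqr ~ "DNQ",
    TRUE ~ "quantified"
  )
  tibble::tibble(
    rate_nmol_l_d = pmax(raw, 0),
    rate_raw = raw,
    lod = lims$lod,
    mqr = lims$mqr,
    status = status
  )
}

#' Detection limit and minimum quantifiable rate for a bulk incubation
#'
#' The LOD (MQR) is the rate that would be measured if the final atom%
#' exceeded the t0 atom% by `k_lod` (`k_mqr`) reference-measurement
#' standard deviations, i.e. the mass balance evaluated at the smallest
#' resolvable enrichment. Both scale linearly with `sd_a_pn_ref` and with
#' the PN concentration.
#'
#' @inheritParams bulk_nfr
#' @return A list with numeric components `lod` and `mqr` (nmol N/l/d).
#' @export
#' @examples
#' nfr_detection_limits(0.3663, 2.3941, 1, 1, sd_a_pn_ref = 5e-4)
nfr_detection_limits <- function(a_pn_t0, a_n2, pn_umol_l, duration_d,
                                 sd_a_pn_ref, k_lod = 3, k_mqr = 10) {
  stopifnot(k_mqr >= k_lod, k_lod > 0)
  if (any(sd_a_pn_ref < 0, na.rm = TRUE)) {
    stop("sd_a_pn_ref must be >= 0", call. = FALSE)
  }
  if (any(a_n2 <= a_pn_t0, na.rm = TRUE)) {
    stop("source-pool atom% must exceed t0 atom%", call. = FALSE)
  }
  denom <- a_n2 - a_pn_t0
  scale <- pn_umol_l * 1000 / duration_d
  list(
    lod = k_lod * sd_a_pn_ref / denom * scale,
    mqr = k_mqr * sd_a_pn_ref / denom * scale
  )
}

#' Compute rates for a table of bulk incubations
#'
#' Vectorised wrapper over [mix_source_pool()], [bulk_nfr()] and
#' [nfr_detection_limits()] for the flat `incubations` table. Columns
#' `a_n2_pct`, `rate_nmol_l_d`, `lod`, `mqr` and `status` are appended.
#'
#' @param incubations Data frame with columns `a_pn_t0_pct`,
#'   `a_pn_final_pct`, `a_enriched_pct`, `v_enriched_l`, `v_ambient_l`,
#'   `pn_umol_l`, `duration_d`, `sd_ref_pct` (plus any identifier columns,
#'   which are preserved).
#' @inheritParams bulk_nfr
#' @return The input tibble with rate columns appended.
#' @export
bulk_nfr_table <- function(incubations, k_lod = 3, k_mqr = 10) {
  need <- c("a_pn_t0_pct", "a_pn_final_pct", "a_enriched_pct",
            "v_enriched_l", "v_ambient_l", "pn_umol_l", "duration_d",
            "sd_ref_pct")
  miss <- setdiff(need, names(incubations))
  if (length(miss)) {
    stop("incubations table missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  inc <- tibble::as_tibble(incubations)
  a_n2 <- mix_source_pool(inc$a_enriched_pct, inc$v_enriched_l,
                          inc$v_ambient_l)
  res <- bulk_nfr(inc$a_pn_t0_pct, inc$a_pn_final_pct, a_n2,
                  inc$pn_umol_l, inc$duration_d, inc$sd_ref_pct,
                  k_lod = k_lod, k_mqr = k_mqr)
  dplyr::bind_cols(inc, tibble::tibble(a_n2_pct = a_n2), res)
}
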