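# Derived hydrochemical quantities and profile operations: excess
# phosphate (P*), analyte censoring, depth integration, mixed-layer depth
# and the Redfield N-to-C equivalence.

#' Excess phosphate P*
#'
#' P* = PO4 - (NO3 + NO2)/16, the phosphate in excess of what Redfield
#' N:P stoichiometry predicts; positive values indicate conditions
#' favourable to N2 fixation. Missing analytes propagate NA.
#'
#' @param po4 Phosphate (umol/l).
#' @param no3no2 Nitrate + nitrite (umol/l).
#' @return P* (umol/l); may be negative.
#' @export
#' @examples
#' p_star(0.88, 9.82) # ~0.27
p_star <- function(po4, no3no2) {
  po4 - no3no2 / 16
}

#' Censor an analyte value against its detection/quantitation limits
#'
#' @param value Measured concentration.
#' @param lod,loq Analyte limits, `lod <= loq`.
#' @return Character status: `"BDL"` (<= LOD), `"DNQ"` (< LOQ) or
#'   `"quantified"`. Values are never altered; callers choose whether to
#'   use raw values or substitute zero for BDL.
#' @export
censor_analyte <- function(value, lod, loq = lod) {
  if (any(lod > loq, na.rm = TRUE)) {
    stop("analyte LOD must not exceed LOQ", call. = FALSE)
  }
  dplyr::case_when(
    is.na(value) ~ NA_character_,
    value <= lod ~ "BDL",
    value < loq ~ "DNQ",
    TRUE ~ "quantified"
  )
}

#' Depth-integrate a concentration or rate profile
#'
#' Trapezoidal integration over depth, with the shallowest sample extended
#' as a constant to the surface (0 m). A per-litre integrand in nmol/l
#' integrates to umol per square metre (1 nmol/l = 1 umol/m^3); copies/l
#' integrate to copies/m^2 x 1e-3 under the same convention, so the
#' returned unit is `integrand unit per litre x 1000 x m`, i.e. per-m^2
#' with the litre-to-m^3 factor folded in.
#'
#' @param depth_m Sample depths (m), any order, non-negative, distinct.
#' @param value Integrand at each depth (per-litre units).
#' @param z_max Integration bound (m). Defaults to the deepest sample.
#'   A shallower bound truncates (with linear interpolation); a deeper
#'   bound requires `extend = TRUE` (constant extrapolation below the
#'   deepest sample).
#' @param extend Allow constant extrapolation beyond the sampled range.
#' @param scale Unit factor applied to the integral: the default 1 turns
#'   nmol/l/d into umol/m^2/d (the x1000 litre-to-m^3 and /1000
#'   nmol-to-umol factors cancel); use `scale = 1000` for copies/l to
#'   copies/m^2.
#' @return Areal value: for `value` in nmol N/l/d the result is
#'   umol N/m^2/d.
#' @export
#' @examples
#' depth_integrate(c(0, 100), c(5, 5))   # 500
#' depth_integrate(c(0, 100), c(10, 0))  # 500
depth_integrate <- function(depth_m, value, z_max = NULL, extend = FALSE,
                            scale = 1) {
  stopifnot(length(depth_m) == length(value))
  keep <- stats::complete.cases(depth_m, value)
  depth_m <- depth_m[keep]
  value <- value[keep]
  if (length(depth_m) < 2 && !extend) {
    stop("need >= 2 depths to integrate (or extend = TRUE)",
         call. = FALSE)
  }
  if (any(depth_m < 0)) stop("depths must be >= 0", call. = FALSE)
  if (anyDuplicated(depth_m)) {
    stop("duplicate depths in profile", call. = FALSE)
  }
  o <- order(depth_m)
  z <- depth_m[o]
  v <- value[o]
  if (is.null(z_max)) z_max <- max(z)
  if (z_max > max(z)) {
    if (!extend) {
      stop("z_max exceeds deepest sample; set extend = TRUE for ",
           "constant extrapolation", call. = FALSE)
    }
    z <- c(z, z_max)
    v <- c(v, v[length(v)])
  } else if (z_max < max(z)) {
    v_at <- stats::approx(z, v, xout = z_max)$y
    keep <- z < z_max
    z <- c(z[keep], z_max)
    v <- c(v[keep], v_at)
  }
  # constant extension of the shallowest sample to the surface
  if (z[1] > 0) {
    z <- c(0, z)
    v <- c(v[1], v)
  }
  scale * pracma::trapz(z, v)
}

#' Mixed-layer depth from a profile
#'
#' Shallowest depth at which the chosen property deviates from its value
#' at the shallowest sample by more than `threshold`, located by linear
#' interpolation between the bracketing samples. Density uses the
#' conventional threshold 0.125 kg/m^3 on sigma-theta; temperature uses
#' 0.2 degC. If no sample exceeds the threshold the deepest sampled depth
#' is returned, flagged `"unstratified"`.
#'
#' @param depth_m Sample depths (m), >= 2 values.
#' @param property Sigma-theta (kg/m^3) or temperature (degC) at each
#'   depth.
#' @param criterion `"density"` (default, threshold on +delta sigma-theta)
#'   or `"temperature"` (threshold on |delta T|).
#' @param threshold Deviation threshold; defaults 0.125 kg/m^3 (density)
#'   or 0.2 degC (temperature).
#' @return A one-row tibble: `mld_m`, `flag` (`"ok"` or `"unstratified"`).
#' @export
mixed_layer_depth <- function(depth_m, property,
                              criterion = c("density", "temperature"),
                              threshold = NULL) {
  criterion <- match.arg(criterion)
  if (is.null(threshold)) {
    threshold <- if (criterion == "density") 0.125 else 0.2
  }
  stopifnot(length(depth_m) == length(property), threshold > 0)
  keep <- stats::complete.cases(depth_m, property)
  depth_m <- depth_m[keep]
  property <- property[keep]
  if (length(depth_m) < 2) {
    stop("need >= 2 depths for a mixed-layer estimate", call. = FALSE)
  }
  o <- order(depth_m)
  z <- depth_m[o]
  p <- property[o]
  dev <- if (criterion == "density") p - p[1] else abs(p - p[1])
  exceeds <- which(dev > threshold)
  if (length(exceeds) == 0) {
    return(tibble::tibble(mld_m = max(z), flag = "unstratified"))
  }
  i <- exceeds[1]
  if (i == 1) {
    return(tibble::tibble(mld_m = z[1], flag = "ok"))
  }
  # linear interpolation between the bracketing samples
  frac <- (threshold - dev[i - 1]) / (dev[i] - dev[i - 1])
  tibble::tibble(mld_m = z[i - 1] + frac * (z[i] - z[i - 1]), flag = "ok")
}

#' Redfield carbon equivalent of a nitrogen rate
#'
#' Converts an N supply to the C production it supports at Redfield
#' C:N = 106:16.
#'
#' @param n_rate Nitrogen rate, e.g. umol N/m^2/d, >= 0.
#' @return Carbon rate in matching units (x 106/16).
#' @export
#' @examples
#' redfield_c_equivalent(16) # 106
redfield_c_equivalent <- function(n_rate) {
  if (any(n_rate < 0, na.rm = TRUE)) {
    stop("nitrogen rate must be non-negative", call. = FALSE)
  }
  n_rate * 106 / 16
}

#' Append P* and analyte censoring flags to a hydrochemistry table
#'
#' @param hydro Data frame with columns `cruise`, `station`, `depth_m`,
#'   `temp_c`, `salinity`, `no3no2_umol_l`, `po4_umol_l`, `chl_ug_l`.
#' @param limits Named list of `c(lod, loq)` per analyte; defaults to the
#'   assay limits used package-wide (NO3+NO2: 0.01/0.04, PO4: 0.01/0.02
#'   umol/l, Chl a: 0.002 ug/l LOD).
#' @return The table with `p_star`, and `*_status` flag columns.
#' @export
hydro_table <- function(hydro,
                        limits = list(no3no2 = c(0.01, 0.04),
                                      po4 = c(0.01, 0.02),
                                      chl = c(0.002, 0.002))) {
  hydro <- tibble::as_tibble(hydro)
  need <- c("cruise", "station", "depth_m", "no3no2_umol_l", "po4_umol_l")
  miss <- setdiff(need, names(hydro))
  if (length(miss)) {
    stop("hydro table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  hydro |>
    dplyr::mutate(
      p_star = p_star(.data$po4_umol_l, .data$no3no2_umol_l),
      no3no2_status = censor_analyte(.data$no3no2_umol_l,
                                     limits$no3no2[1], limits$no3no2[2]),
      po4_status = censor_analyte(.data$po4_umol_l, limits$po4[1],
                                  limits$po4[2]),
      chl_status = if ("chl_ug_l" %in% names(hydro)) {
        censor_analyte(.data$chl_ug_l, limits$chl[1], limits$chl[2])
      } else {
        NA_character_
      }
    )
}
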