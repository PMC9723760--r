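# Orchestration: I/O contracts, configuration, validation, and the
# end-to-end analysis tying the stages together.

#' Run configuration
#'
#' Collects the tunable constants of the analysis with their documented
#' defaults. The full configuration is serialised (with a hash) into
#' every output table for provenance.
#'
#' @param nat_abundance_pct Atom% 15N of ambient dissolved N2.
#' @param dilution_fraction Isotope-dilution fraction (0.75 => x4).
#' @param k_lod,k_mqr LOD/MQR multipliers for rate censoring.
#' @param convention Copies-per-cell from [copy_number_convention()].
#' @param quota A [quota_model()].
#' @param mld_criterion `"density"` or `"temperature"`.
#' @param bdl_policy BDL-association policy for station means.
#' @param dnq_policy DNQ qPCR policy for scaling.
#' @param seed Seed for any stochastic stage.
#' @return A list of class `run_config` with a `hash` element.
#' @export
run_config <- function(nat_abundance_pct = NAT_ABUNDANCE_15N,
                       dilution_fraction = 0.75,
                       k_lod = 3, k_mqr = 10,
                       convention = copy_number_convention(),
                       quota = quota_model(),
                       mld_criterion = "density",
                       bdl_policy = "zero",
                       dnq_policy = "exclude",
                       seed = 1L) {
  stopifnot(nat_abundance_pct >= 0, nat_abundance_pct < 100,
            dilution_fraction >= 0, dilution_fraction < 1,
            k_mqr >= k_lod, k_lod > 0)
  cfg <- list(nat_abundance_pct = nat_abundance_pct,
              dilution_fraction = dilution_fraction,
              k_lod = k_lod, k_mqr = k_mqr,
              convention = convention, quota = quota,
              mld_criterion = mld_criterion,
              bdl_policy = bdl_policy, dnq_policy = dnq_policy,
              seed = seed)
  cfg$hash <- rlang::hash(cfg)
  structure(cfg, class = "run_config")
}

#' Validate an input-table bundle
#'
#' Diagnostic only: reports missing columns, unit-range violations
#' (atom% outside `[0, 100]`, negative concentrations or copies),
#' non-monotone/duplicate depths and duplicate qPCR keys. An empty
#' tibble means a well-formed bundle.
#'
#' @param bundle Named list with any of `hydro`, `incubations`,
#'   `nanosims_rois`, `qpcr`.
#' @return Tibble of diagnostics: `table`, `check`, `detail`.
#' @export
validate_tables <- function(bundle) {
  out <- list()
  note <- function(table, check, detail) {
    out[[length(out) + 1]] <<- tibble::tibble(
      table = table, check = check, detail = detail)
  }
  need_cols <- list(
    hydro = c("cruise", "station", "depth_m", "no3no2_umol_l",
              "po4_umol_l"),
    incubations = c("cruise", "station", "a_pn_t0_pct",
                    "a_pn_final_pct", "a_enriched_pct", "v_enriched_l",
                    "v_ambient_l", "pn_umol_l", "duration_d",
                    "sd_ref_pct"),
    nanosims_rois = c("cruise", "station", "group", "association_id",
                      "partner", "biovolume_um3", "is_reference",
                      "a_n2_pct", "duration_d"),
    qpcr = c("cruise", "station", "group", "copies_per_l", "lod", "loq")
  )
  for (tn in names(need_cols)) {
    tb <- bundle[[tn]]
    if (is.null(tb)) next
    miss <- setdiff(need_cols[[tn]], names(tb))
    if (length(miss)) {
      note(tn, "missing_columns", paste(miss, collapse = ", "))
    }
  }
  inc <- bundle$incubations
  if (!is.null(inc)) {
    for (col in intersect(c("a_pn_t0_pct", "a_pn_final_pct",
                            "a_enriched_pct"), names(inc))) {
      bad <- which(inc[[col]] < 0 | inc[[col]] > 100)
      if (length(bad)) {
        note("incubations", "atom_pct_range",
             paste0(col, " out of [0,100] at row(s) ",
                    paste(bad, collapse = ",")))
      }
    }
    if ("pn_umol_l" %in% names(inc)) {
      bad <- which(inc$pn_umol_l <= 0)
      if (length(bad)) {
        note("incubations", "nonpositive_pn",
             paste("row(s)", paste(bad, collapse = ",")))
      }
    }
  }
  hy <- bundle$hydro
  if (!is.null(hy) && all(c("station", "depth_m") %in% names(hy))) {
    dup <- hy |>
      dplyr::count(.data$cruise, .data$station, .data$depth_m) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup)) {
      note("hydro", "duplicate_depths",
           paste(dup$station, dup$depth_m, sep = "@",
                 collapse = "; "))
    }
    for (col in intersect(c("no3no2_umol_l", "po4_umol_l", "chl_ug_l"),
                          names(hy))) {
      bad <- which(hy[[col]] < -0.05)
      if (length(bad)) {
        note("hydro", "negative_concentration",
             paste0(col, " at row(s) ", paste(bad, collapse = ",")))
      }
    }
  }
  qp <- bundle$qpcr
  if (!is.null(qp)) {
    if ("copies_per_l" %in% names(qp)) {
      bad <- which(qp$copies_per_l < 0)
      if (length(bad)) {
        note("qpcr", "negative_copies",
             paste("row(s)", paste(bad, collapse = ",")))
      }
    }
    key <- intersect(c("cruise", "station", "depth_m", "group"),
                     names(qp))
    if (length(key) >= 3) {
      dup <- qp |>
        dplyr::count(dplyr::across(dplyr::all_of(key))) |>
        dplyr::filter(.data$n > 1)
      if (nrow(dup)) {
        note("qpcr", "duplicate_keys", paste(nrow(dup), "duplicate",
                                             "station/depth/group rows"))
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(table = character(), check = character(),
                          detail = character()))
  }
  dplyr::bind_rows(out)
}

#' Run the full analysis pipeline on an input bundle
#'
#' Executes the stages in order: bulk rates from the incubations table,
#' single-cell symbiosis rates from the nanoSIMS ROI table, scaling to
#' volumetric rates and contributions through the qPCR table, hydro
#' derived quantities (P*, censoring) with per-station profile metrics
#' (mixed-layer depth, depth-integrated rates), and the association
#' screen between surface abundances. Stages with missing inputs are
#' skipped with a warning. Deterministic throughout for a fixed config.
#'
#' @param bundle Named list of input tibbles (`hydro`, `incubations`,
#'   `nanosims_rois`, `qpcr`); see [generate_survey()] or
#'   [read_bundle()].
#' @param config A [run_config()].
#' @return Named list: `bulk_rates`, `symbiosis_rates`, `contributions`,
#'   `hydro`, `station_metrics`, `associations`, `diagnostics`, `log`
#'   (one row per stage with row counts), `config`.
#' @export
run_pipeline <- function(bundle, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  diag <- validate_tables(bundle)
  if (nrow(diag)) {
    warning("input diagnostics reported; see $diagnostics",
            call. = FALSE)
  }
  logs <- list()
  stage <- function(name, n_in, n_out) {
    logs[[length(logs) + 1]] <<- tibble::tibble(
      stage = name, rows_in = n_in, rows_out = n_out)
  }
  stamp <- function(tb) {
    if (is.null(tb)) return(NULL)
    tb$config_hash <- config$hash
    tb
  }

  bulk_rates <- NULL
  if (!is.null(bundle$incubations)) {
    bulk_rates <- bulk_nfr_table(bundle$incubations,
                                 k_lod = config$k_lod,
                                 k_mqr = config$k_mqr)
    stage("bulk_rates", nrow(bundle$incubations), nrow(bulk_rates))
  }

  symbiosis_rates <- NULL
  if (!is.null(bundle$nanosims_rois)) {
    symbiosis_rates <- symbiosis_rate_table(
      bundle$nanosims_rois, q = config$quota, k_lod = config$k_lod,
      bdl_policy = config$bdl_policy,
      dilution_fraction = config$dilution_fraction)
    stage("symbiosis_rates", nrow(bundle$nanosims_rois),
          nrow(symbiosis_rates))
  }

  contributions <- NULL
  if (!is.null(symbiosis_rates) && !is.null(bundle$qpcr) &&
      nrow(bundle$qpcr) > 0 && !is.null(bulk_rates)) {
    # scale against the shallowest bulk rate of each station
    bulk_surface <- bulk_rates |>
      dplyr::group_by(.data$cruise, .data$station) |>
      dplyr::slice_min(.data$depth_m, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::transmute(.data$cruise, .data$station,
                       .data$rate_nmol_l_d, sd = NA_real_, .data$lod,
                       .data$status)
    qpcr_surface <- bundle$qpcr |>
      dplyr::group_by(.data$cruise, .data$station, .data$group) |>
      dplyr::slice_min(.data$depth_m, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    rates_in <- symbiosis_rates |>
      dplyr::transmute(.data$cruise, .data$station, .data$group,
                       n_cells = .data$n_cells,
                       mean_rate = .data$mean_rate, sd = .data$sd)
    contributions <- group_contributions(
      rates_in, qpcr_surface, bulk_surface,
      convention = config$convention,
      dilution_fraction = config$dilution_fraction,
      dnq_policy = config$dnq_policy)
    stage("contributions", nrow(rates_in), nrow(contributions))
  } else if (!is.null(symbiosis_rates)) {
    warning("qPCR or bulk table missing/empty: contributions skipped",
            call. = FALSE)
  }

  hydro <- NULL
  station_metrics <- NULL
  if (!is.null(bundle$hydro)) {
    hydro <- hydro_table(bundle$hydro)
    mld_col <- if (config$mld_criterion == "density" &&
                   "sigma_theta" %in% names(hydro)) {
      "sigma_theta"
    } else {
      "temp_c"
    }
    mld_crit <- if (mld_col == "sigma_theta") "density" else
      "temperature"
    station_metrics <- hydro |>
      dplyr::group_by(.data$cruise, .data$station) |>
      dplyr::reframe(mixed_layer_depth(.data$depth_m,
                                       .data[[mld_col]],
                                       criterion = mld_crit)) |>
      dplyr::rename(mld_flag = "flag")
    if (!is.null(bulk_rates) && "depth_m" %in% names(bulk_rates)) {
      integ <- bulk_rates |>
        dplyr::group_by(.data$cruise, .data$station) |>
        dplyr::summarise(
          nfr_areal_umol_m2_d = if (dplyr::n() >= 2) {
            depth_integrate(.data$depth_m, .data$rate_nmol_l_d)
          } else {
            NA_real_
          },
          .groups = "drop")
      station_metrics <- dplyr::left_join(
        station_metrics, integ, by = c("cruise", "station"))
      station_metrics$new_production_umol_c_m2_d <-
        redfield_c_equivalent(
          pmax(station_metrics$nfr_areal_umol_m2_d, 0))
    }
    stage("hydro", nrow(bundle$hydro), nrow(hydro))
  }

  associations <- NULL
  if (!is.null(bundle$qpcr) && nrow(bundle$qpcr) > 0) {
    wide <- bundle$qpcr |>
      dplyr::select(dplyr::all_of(c("cruise", "station", "group",
                                    "copies_per_l")),
                    dplyr::any_of("depth_m")) |>
      tidyr::pivot_wider(names_from = "group",
                         values_from = "copies_per_l")
    gnames <- setdiff(names(wide), c("cruise", "station", "depth_m"))
    if (length(gnames) >= 2 &&
        sum(stats::complete.cases(wide[gnames[1:2]])) >= 3) {
      associations <- association_screen(
        wide, pairs = tibble::tibble(var1 = gnames[1],
                                     var2 = gnames[2]))
      stage("associations", nrow(wide), nrow(associations))
    }
  }

  list(
    bulk_rates = stamp(bulk_rates),
    symbiosis_rates = stamp(symbiosis_rates),
    contributions = stamp(contributions),
    hydro = stamp(hydro),
    station_metrics = stamp(station_metrics),
    associations = stamp(associations),
    diagnostics = diag,
    log = if (length(logs)) dplyr::bind_rows(logs) else
      tibble::tibble(stage = character(), rows_in = integer(),
                     rows_out = integer()),
    config = config
  )
}

#' Read an input bundle from delimited files
#'
#' @param dir Directory holding `hydro.csv`, `incubations.csv`,
#'   `nanosims_rois.csv`, `qpcr.csv` (any subset; UTF-8, comma
#'   delimited, one header line, empty fields as missing).
#' @return Named list of tibbles (absent files are omitted).
#' @export
read_bundle <- function(dir) {
  stopifnot(dir.exists(dir))
  tables <- c("hydro", "incubations", "nanosims_rois", "qpcr", "truth")
  out <- list()
  for (tn in tables) {
    f <- file.path(dir, paste0(tn, ".csv"))
    if (file.exists(f)) {
      out[[tn]] <- readr::read_csv(f, show_col_types = FALSE,
                                   progress = FALSE)
      if ("station" %in% names(out[[tn]])) {
        out[[tn]]$station <- as.character(out[[tn]]$station)
      }
    }
  }
  out
}

#' Write a bundle or result list to delimited files
#'
#' @param x Named list of data frames.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_bundle <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (tn in names(x)) {
    if (!is.data.frame(x[[tn]])) next
    f <- file.path(dir, paste0(tn, ".csv"))
    readr::write_csv(x[[tn]], f, na = "")
    paths <- c(paths, f)
  }
  invisible(paths)
}
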