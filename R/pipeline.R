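# End-to-end orchestration: QC -> annual exposure -> PM2.5 -> burden ->
# regional roll-up -> CSV reports, with a run manifest and bit-stable
# outputs. Optional dust branch. Display rounding (AP to 1 decimal of
# a percent, cases to integers) happens only at serialization; every
# computed table is also written at full precision.

#' Run the burden pipeline from a configuration
#'
#' @param config Path to a YAML file, or an equivalent named list, with
#'   keys:
#'   \describe{
#'     \item{stations}{path to a station-record CSV (see
#'       [read_station_csv()]).}
#'     \item{endpoints}{list of `endpoint` / `pollutant` / `group`
#'       entries resolved against the packaged CRF, incidence and
#'       population tables; default: every packaged CRF, with the
#'       children's population for endpoints naming children and the
#'       adult population otherwise.}
#'     \item{distribution}{`"mean"` (single category at the zone annual
#'       mean; default) or `"binned"` (10 ug/m3 bins of valid daily
#'       values).}
#'     \item{ratios}{optional path to a measured-ratio CSV; combined
#'       with the packaged priors by inverse variance. Default: priors
#'       alone.}
#'     \item{dust}{optional path to a monthly dust CSV; adds the dust
#'       branch (annual contribution and burden share).}
#'     \item{include_invalid_years}{logical; keep zone-years failing the
#'       completeness rule (default `FALSE`, exclusions logged).}
#'     \item{exceedance_threshold}{daily reference level, default 45.}
#'   }
#' @param out_dir Output directory, created if needed. No partial
#'   outputs: the manifest is written last and lists every stage.
#' @return Invisibly, a list with the computed tables and the manifest.
#' @export
run_burden_pipeline <- function(config, out_dir) {
  config_path <- NULL
  if (is.character(config) && length(config) == 1L) {
    config_path <- config
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  problems <- character()
  if (is.null(config$stations)) problems <- c(problems, "missing key 'stations'")
  else if (!file.exists(config$stations)) {
    problems <- c(problems, paste0("stations file not found: ", config$stations))
  }
  dist_mode <- config$distribution %||% "mean"
  if (!dist_mode %in% c("mean", "binned")) {
    problems <- c(problems, paste0("unknown distribution mode: ", dist_mode))
  }
  for (key in c("ratios", "dust")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      problems <- c(problems, sprintf("%s file not found: %s", key, config[[key]]))
    }
  }
  if (length(problems) > 0L) {
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  }

  tables <- fixture_tables()
  warnings_log <- character()
  log_stage <- function(stage, msg) {
    message(sprintf("[%s] %s", stage, msg))
  }

  # --- QC ---------------------------------------------------------------
  records <- read_station_csv(config$stations)
  qc <- qc_filter(records)
  log_stage("qc", sprintf("%d records read, %d valid, %d rejected",
                          qc$counts[["n_input"]], qc$counts[["n_valid"]],
                          qc$counts[["n_rejected"]]))
  valid <- qc$valid
  years <- sort(unique(as.integer(format(valid$date, "%Y"))))
  zones <- intersect(pm_zones(), unique(valid$zone))

  rec_year <- as.integer(format(valid$date, "%Y"))
  annual <- do.call(rbind, lapply(zones, function(z) {
    do.call(rbind, lapply(years, function(y) {
      annual_summary(valid[valid$zone == z & rec_year == y, , drop = FALSE],
                     z, y,
                     exceedance_threshold = config$exceedance_threshold %||% 45)
    }))
  }))
  include_invalid <- isTRUE(config$include_invalid_years)
  excluded <- annual[!annual$is_valid, c("zone", "year")]
  if (nrow(excluded) > 0L && !include_invalid) {
    msg <- paste(sprintf("%s/%d", excluded$zone, excluded$year), collapse = ", ")
    warnings_log <- c(warnings_log,
                      paste0("zone-years excluded for incompleteness: ", msg))
    log_stage("qc", paste0("excluding incomplete zone-years: ", msg))
  }

  # --- ratios -----------------------------------------------------------
  ratios <- fixture_ratio_priors(tables)
  if (!is.null(config$ratios)) {
    measured <- read_ratio_csv(config$ratios)
    ratios <- c(lapply(measured, function(m) {
      pri <- tryCatch(lookup_ratio(ratios, m$zone, "all", quiet = TRUE),
                      error = function(e) NULL)
      if (is.null(pri) || m$sd <= 0 || pri$sd <= 0) m
      else combine_ratio_with_prior(m, pri)
    }), ratios)
    log_stage("ratios", sprintf("%d measured ratio(s) combined with priors",
                                length(measured)))
  }

  # --- endpoints --------------------------------------------------------
  endpoints <- config$endpoints
  if (is.null(endpoints)) {
    endpoints <- lapply(seq_len(nrow(tables$crf)), function(i) {
      ep <- tables$crf$endpoint[i]
      list(endpoint = ep, pollutant = tables$crf$pollutant[i],
           group = if (grepl("children", ep)) "children" else "adults")
    })
  }

  # --- burden -----------------------------------------------------------
  burden_rows <- list()
  for (ep in endpoints) {
    cr <- fixture_crf(ep$endpoint, ep$pollutant, tables)
    inc_tab <- tables$incidence
    for (z in zones) {
      inc <- inc_tab$rate_per_100k[inc_tab$endpoint == ep$endpoint &
                                     inc_tab$zone == z]
      if (length(inc) != 1L) {
        warnings_log <- c(warnings_log, sprintf(
          "no incidence for endpoint '%s' in zone %s; skipped", ep$endpoint, z))
        next
      }
      pop <- fixture_population(z, ep$group %||% "all", tables)
      for (y in years) {
        a <- annual[annual$zone == z & annual$year == y, ]
        if (nrow(a) != 1L || (!a$is_valid && !include_invalid) || is.na(a$mean)) next
        zday <- valid[valid$zone == z &
                        as.integer(format(valid$date, "%Y")) == y, "pm10"]
        if (ep$pollutant == "PM2.5") {
          a_use <- a; a_use$is_valid <- TRUE
          est <- estimate_pm25_annual(a_use, ratios, quiet = TRUE)
          conc_mean <- est$pm25
          r_used <- conc_mean / a$mean
          daily <- zday * r_used
        } else {
          conc_mean <- a$mean
          daily <- zday
        }
        dist <- if (dist_mode == "binned") binned_exposure(daily)
                else exposure_dist(conc_mean, 1)
        burden_rows[[length(burden_rows) + 1L]] <-
          burden_with_ci(dist, cr, inc, pop, zone = z, year = y)
      }
    }
  }
  if (length(burden_rows) == 0L) stop("no burden rows computed; nothing to write")
  burden <- do.call(rbind, burden_rows)
  log_stage("burden", sprintf("%d zone-year-endpoint rows", nrow(burden)))

  # --- regional roll-up -------------------------------------------------
  pops_all <- lapply(zones, fixture_population, group = "all", tables = tables)
  regional <- do.call(rbind, lapply(split(burden,
                                          list(burden$endpoint, burden$year),
                                          drop = TRUE),
                                    regional_rollup, zone_pops = pops_all))
  row.names(regional) <- NULL

  # --- dust branch ------------------------------------------------------
  dust_tab <- NULL
  if (!is.null(config$dust)) {
    dust <- read_dust_csv(config$dust)
    dust_tab <- do.call(rbind, lapply(zones, function(z) {
      dz <- dust[dust$zone == z, , drop = FALSE]
      do.call(rbind, lapply(intersect(years, unique(dz$year)), function(y) {
        a <- annual[annual$zone == z & annual$year == y, ]
        if (nrow(a) != 1L || is.na(a$mean)) return(NULL)
        inc <- annual_dust_increase(dz, a$mean, y)
        data.frame(zone = z, year = y, dust_abs_ugm3 = inc$abs,
                   dust_rel_pct = inc$rel, stringsAsFactors = FALSE)
      }))
    }))
    log_stage("dust", sprintf("%d zone-year dust rows", NROW(dust_tab)))
  }

  # --- outputs ----------------------------------------------------------
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, file) {
    utils::write.csv(df, file.path(out_dir, file), row.names = FALSE,
                     quote = FALSE)
    file
  }
  files <- c(wr(annual, "annual_exposure.csv"),
             wr(as.data.frame(burden), "burden_zone.csv"),
             wr(as.data.frame(regional), "burden_regional.csv"),
             wr(round_burden_report(burden), "burden_zone_report.csv"))
  if (!is.null(dust_tab)) files <- c(files, wr(dust_tab, "dust_contribution.csv"))

  manifest <- list(
    package = "pmhia",
    version = as.character(utils::packageVersion("pmhia")),
    config_digest = unname(if (!is.null(config_path)) tools::md5sum(config_path)
                           else digest_of_object(config)),
    inputs = Filter(Negate(is.null),
                    list(stations = config$stations, ratios = config$ratios,
                         dust = config$dust)),
    stages = list(qc = as.list(qc$counts),
                  annual = nrow(annual),
                  burden = nrow(burden),
                  regional = nrow(regional),
                  dust = NROW(dust_tab)),
    outputs = files,
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(annual = annual, burden = burden, regional = regional,
                 dust = dust_tab, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable digest of an in-memory config (md5 of its canonical YAML)
digest_of_object <- function(x) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(x, tf)
  unname(tools::md5sum(tf))
}

#' Display rounding of a burden table
#'
#' Attributable proportions become percentages with one decimal and
#' case counts integers, as in published burden tables. Rounding
#' happens here and only here; computations stay at full precision.
#'
#' @param burden `burden_result` data.frame.
#' @return data.frame ready for report serialization.
#' @export
round_burden_report <- function(burden) {
  data.frame(endpoint = burden$endpoint, zone = burden$zone,
             year = burden$year,
             ap_pct = sprintf("%.1f%% (%.1f-%.1f%%)",
                              100 * burden$ap_central, 100 * burden$ap_low,
                              100 * burden$ap_high),
             cases = sprintf("%d (%d-%d)", round(burden$cases_central),
                             round(burden$cases_low), round(burden$cases_high)),
             rate_per_100k = round(burden$rate_per_100k, 1),
             stringsAsFactors = FALSE)
}
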