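# Exposure quality control: validity screening of daily 24-h PM10 samples
# and monthly/annual aggregation with completeness accounting.

#' Coerce and validate a table of daily station records
#'
#' Checks types and invariants of a station-record table (one row per
#' daily 24-h PM10 sample) and normalises it: `date` becomes `Date`,
#' a missing `reject_flag` column becomes `"none"`, empty flags become
#' `"none"`.
#'
#' @param records data.frame with columns `station_id`, `zone`, `date`,
#'   `pm10` (ug/m3, may be `NA` for missing), `sample_hours` and
#'   optionally `reject_flag` (`"none"`, `"rare_source"`,
#'   `"power_outage"`).
#' @return The normalised data.frame.
#' @details Malformed dates and negative concentrations are record-level
#'   errors: the error message names the offending station and date so a
#'   data manager can trace the sample.
#' @export
as_station_records <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("station_id", "zone", "date", "pm10", "sample_hours")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop("station records lack column(s): ", paste(miss, collapse = ", "))
  }
  if (!("reject_flag" %in% names(records))) records$reject_flag <- "none"
  records$reject_flag[is.na(records$reject_flag) |
                        records$reject_flag == ""] <- "none"
  bad_flag <- !(records$reject_flag %in% c("none", "rare_source", "power_outage"))
  if (any(bad_flag)) {
    stop("unknown reject_flag value(s): ",
         paste(unique(records$reject_flag[bad_flag]), collapse = ", "))
  }
  bad_zone <- !(records$zone %in% pm_zones())
  if (any(bad_zone)) {
    stop("unknown zone(s): ", paste(unique(records$zone[bad_zone]), collapse = ", "),
         " (expected ", paste(pm_zones(), collapse = "/"), ")")
  }
  dt <- tryCatch(as.Date(records$date), error = function(e) rep(as.Date(NA), nrow(records)),
                 warning = function(w) suppressWarnings(as.Date(records$date)))
  bad_date <- is.na(dt) & !is.na(records$date)
  if (any(bad_date)) {
    i <- which(bad_date)[1L]
    stop(sprintf("malformed date '%s' for station %s",
                 records$date[i], records$station_id[i]))
  }
  records$date <- dt
  records$pm10 <- as.numeric(records$pm10)
  neg <- !is.na(records$pm10) & records$pm10 < 0
  if (any(neg)) {
    i <- which(neg)[1L]
    stop(sprintf("negative PM10 concentration (%g) for station %s on %s",
                 records$pm10[i], records$station_id[i], format(records$date[i])))
  }
  records$sample_hours <- as.numeric(records$sample_hours)
  bad_h <- !is.na(records$sample_hours) &
    (records$sample_hours <= 0 | records$sample_hours > 24)
  if (any(bad_h)) {
    i <- which(bad_h)[1L]
    stop(sprintf("sample_hours outside (0, 24] (%g) for station %s on %s",
                 records$sample_hours[i], records$station_id[i],
                 format(records$date[i])))
  }
  records
}

#' Validity of daily PM10 records
#'
#' A daily 24-h sample is valid when its sampling time lies in the
#' acceptance window (default 22-24 h, i.e. a nominal 23 +/- 1 h run),
#' it carries no rejection flag (rare local emission source near the
#' station, or a power outage longer than 2 h during collection), and a
#' nonnegative concentration was reported.
#'
#' @param records Station-record table (see [as_station_records()]).
#' @param min_hours,max_hours Acceptance window for the sampling
#'   duration, in hours; both bounds inclusive.
#' @return Logical vector, one element per record. Pure: `records` is
#'   not modified.
#' @examples
#' r <- data.frame(station_id = "s1", zone = "coastal",
#'                 date = "2015-01-01", pm10 = 30, sample_hours = 23)
#' validate_daily_record(r)
#' @export
validate_daily_record <- function(records, min_hours = 22, max_hours = 24) {
  stopifnot(min_hours < max_hours)
  records <- as_station_records(records)
  ok_hours <- !is.na(records$sample_hours) &
    records$sample_hours >= min_hours & records$sample_hours <= max_hours
  ok_flag <- records$reject_flag == "none"
  ok_pm <- !is.na(records$pm10) & records$pm10 >= 0
  ok_hours & ok_flag & ok_pm
}

#' Split records into valid and rejected with exact bookkeeping
#'
#' @inheritParams validate_daily_record
#' @return List with `valid` and `rejected` record tables and a
#'   `counts` vector (`n_input`, `n_valid`, `n_rejected`);
#'   `n_valid + n_rejected == n_input` always.
#' @export
qc_filter <- function(records, min_hours = 22, max_hours = 24) {
  records <- as_station_records(records)
  ok <- validate_daily_record(records, min_hours, max_hours)
  list(valid = records[ok, , drop = FALSE],
       rejected = records[!ok, , drop = FALSE],
       counts = c(n_input = nrow(records),
                  n_valid = sum(ok),
                  n_rejected = sum(!ok)))
}

#' Number of scheduled samples in a year under a fixed cadence
#'
#' @param year Calendar year.
#' @param cadence_days One sample every `cadence_days` days (default 3,
#'   the routine 1-working-day-in-3 gravimetric schedule).
#' @return Integer count of scheduled sampling days.
#' @export
scheduled_samples <- function(year, cadence_days = 3) {
  ndays <- as.integer(as.Date(sprintf("%d-12-31", year)) -
                        as.Date(sprintf("%d-01-01", year))) + 1L
  as.integer(ceiling(ndays / cadence_days))
}

#' Completeness threshold for a valid annual mean
#'
#' The annual mean of a zone-year is considered valid when at least 75%
#' of the scheduled samples were retained, and never fewer than 92
#' valid samples (75% of the nominal every-third-day schedule).
#'
#' @inheritParams scheduled_samples
#' @return Integer minimum number of valid samples.
#' @export
completeness_threshold <- function(year, cadence_days = 3) {
  max(92L, as.integer(ceiling(0.75 * scheduled_samples(year, cadence_days))))
}

#' Annual zone-level exposure summary
#'
#' Aggregates valid daily records of one zone and year into the annual
#' mean and standard deviation, with completeness accounting. All valid
#' daily records in the zone are pooled (stations are not averaged
#' first), so stations contribute in proportion to their completeness.
#'
#' @param records Valid station records (already screened with
#'   [validate_daily_record()]); rows of other zones/years are dropped
#'   with a warning.
#' @param zone,year Zone label and calendar year summarised.
#' @param completeness_min Minimum valid samples for `is_valid`;
#'   default [completeness_threshold()] for `year`.
#' @param exceedance_threshold Daily reference level (ug/m3) for
#'   `exceedance_fraction`; default 45 (WHO 24-h PM10 guideline).
#' @return One-row data.frame: `zone`, `year`, `mean`, `sd`, `n_valid`,
#'   `n_scheduled`, `is_valid`, `exceedance_fraction`. With no valid
#'   records `mean` and `sd` are `NA` (never a silent zero) and
#'   `is_valid` is `FALSE`. `sd` uses the n-1 denominator and is 0 for
#'   a single record.
#' @export
annual_summary <- function(records, zone, year,
                           completeness_min = NULL,
                           exceedance_threshold = 45,
                           cadence_days = 3) {
  stopifnot(zone %in% pm_zones(), length(year) == 1L)
  if (is.null(completeness_min)) {
    completeness_min <- completeness_threshold(year, cadence_days)
  }
  n_sched <- scheduled_samples(year, cadence_days)
  if (nrow(records) > 0L) {
    records <- as_station_records(records)
    keep <- records$zone == zone &
      as.integer(format(records$date, "%Y")) == as.integer(year)
    if (any(!keep)) {
      warning(sprintf("dropping %d record(s) outside %s/%d",
                      sum(!keep), zone, year))
    }
    records <- records[keep, , drop = FALSE]
  }
  n <- nrow(records)
  if (n == 0L) {
    return(data.frame(zone = zone, year = as.integer(year),
                      mean = NA_real_, sd = NA_real_, n_valid = 0L,
                      n_scheduled = n_sched, is_valid = FALSE,
                      exceedance_fraction = NA_real_,
                      stringsAsFactors = FALSE))
  }
  x <- records$pm10
  data.frame(zone = zone, year = as.integer(year),
             mean = mean(x),
             sd = if (n == 1L) 0 else stats::sd(x),
             n_valid = n,
             n_scheduled = n_sched,
             is_valid = n >= completeness_min,
             exceedance_fraction = mean(x > exceedance_threshold),
             stringsAsFactors = FALSE)
}

#' Fraction of daily values exceeding a reference level
#'
#' @param pm10 Numeric vector of valid daily concentrations (ug/m3), or
#'   a station-record table.
#' @param threshold Reference level (ug/m3); exceedance is strict
#'   (`> threshold`).
#' @return Proportion in \[0, 1\].
#' @export
exceedance_fraction <- function(pm10, threshold) {
  if (is.data.frame(pm10)) pm10 <- as_station_records(pm10)$pm10
  pm10 <- pm10[!is.na(pm10)]
  if (length(pm10) == 0L) stop("exceedance fraction of an empty record set is undefined")
  mean(pm10 > threshold)
}

#' Monthly zone-level exposure summary
#'
#' @inheritParams annual_summary
#' @param month Calendar month 1-12.
#' @return One-row data.frame `zone`, `year`, `month`, `mean`,
#'   `n_valid`; empty months yield `mean = NA`, `n_valid = 0`.
#' @export
monthly_summary <- function(records, zone, year, month) {
  stopifnot(zone %in% pm_zones(), month >= 1, month <= 12)
  if (nrow(records) > 0L) {
    records <- as_station_records(records)
    keep <- records$zone == zone &
      as.integer(format(records$date, "%Y")) == as.integer(year) &
      as.integer(format(records$date, "%m")) == as.integer(month)
    records <- records[keep, , drop = FALSE]
  }
  n <- nrow(records)
  data.frame(zone = zone, year = as.integer(year), month = as.integer(month),
             mean = if (n == 0L) NA_real_ else mean(records$pm10),
             n_valid = n, stringsAsFactors = FALSE)
}
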