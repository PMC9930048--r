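# CSV readers and writers. One canonical dialect: comma separators,
# UTF-8, "." decimals, ISO-8601 dates, empty cell = missing. Readers
# validate headers exactly and report bad lines by line number (first
# 20), so a malformed export fails loudly and traceably.

check_header <- function(path, expected) {
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  if (!identical(trimws(hdr), expected)) {
    stop(sprintf("%s: header must be exactly '%s' (got '%s')",
                 path, paste(expected, collapse = ","),
                 paste(hdr, collapse = ",")))
  }
}

report_bad_lines <- function(path, bad, why) {
  if (!any(bad)) return(invisible())
  lines <- which(bad) + 1L  # header is line 1
  shown <- utils::head(lines, 20L)
  stop(sprintf("%s: %d bad line(s) (%s); first %d: %s",
               path, sum(bad), why, length(shown),
               paste(shown, collapse = ", ")))
}

#' Read a daily station-record CSV
#'
#' Expected header: `station_id,zone,date,pm10_ugm3,sample_hours,reject_flag`.
#'
#' @param path CSV file path.
#' @return Validated station-record table ([as_station_records()]).
#' @export
read_station_csv <- function(path) {
  check_header(path, c("station_id", "zone", "date", "pm10_ugm3",
                       "sample_hours", "reject_flag"))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  pm <- suppressWarnings(as.numeric(raw$pm10_ugm3))
  report_bad_lines(path, !is.na(raw$pm10_ugm3) & raw$pm10_ugm3 != "" & is.na(pm),
                   "non-numeric pm10_ugm3")
  hrs <- suppressWarnings(as.numeric(raw$sample_hours))
  report_bad_lines(path, is.na(hrs), "non-numeric sample_hours")
  dt <- suppressWarnings(as.Date(raw$date))
  report_bad_lines(path, is.na(dt), "malformed date")
  as_station_records(data.frame(station_id = raw$station_id, zone = raw$zone,
                                date = dt, pm10 = pm, sample_hours = hrs,
                                reject_flag = raw$reject_flag,
                                stringsAsFactors = FALSE))
}

#' Write a station-record table
#'
#' Inverse of [read_station_csv()]: `write -> read` is the identity on
#' a valid table.
#'
#' @param records Station-record table.
#' @param path Output CSV path.
#' @export
write_station_csv <- function(records, path) {
  records <- as_station_records(records)
  out <- data.frame(station_id = records$station_id, zone = records$zone,
                    date = format(records$date, "%Y-%m-%d"),
                    pm10_ugm3 = records$pm10,
                    sample_hours = records$sample_hours,
                    reject_flag = records$reject_flag)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a daily health-series CSV
#'
#' Expected header: `zone,date,deaths,pm10_ugm3`.
#'
#' @param path CSV file path.
#' @return List of [health_series()], one per zone.
#' @export
read_health_csv <- function(path) {
  check_header(path, c("zone", "date", "deaths", "pm10_ugm3"))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  deaths <- suppressWarnings(as.numeric(raw$deaths))
  report_bad_lines(path, is.na(deaths) | deaths < 0 | deaths != round(deaths),
                   "deaths not a nonnegative integer")
  pm <- suppressWarnings(as.numeric(raw$pm10_ugm3))
  report_bad_lines(path, is.na(pm), "non-numeric pm10_ugm3")
  dt <- suppressWarnings(as.Date(raw$date))
  report_bad_lines(path, is.na(dt), "malformed date")
  lapply(split(seq_len(nrow(raw)), raw$zone), function(i) {
    o <- i[order(dt[i])]
    health_series(raw$zone[o[1L]], dt[o], deaths[o], pm[o])
  })
}

#' Read a monthly dust-PM2.5 CSV
#'
#' Expected header: `zone,year,month,dust_pm25_ugm3`.
#'
#' @param path CSV file path.
#' @return Validated dust table ([as_dust_series()]).
#' @export
read_dust_csv <- function(path) {
  check_header(path, c("zone", "year", "month", "dust_pm25_ugm3"))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_dust_series(data.frame(zone = raw$zone, year = as.integer(raw$year),
                            month = as.integer(raw$month),
                            dust_pm25 = as.numeric(raw$dust_pm25_ugm3),
                            stringsAsFactors = FALSE))
}

#' Read a measured ratio CSV
#'
#' Expected header: `zone,month,ratio,sd,n,source`.
#'
#' @param path CSV file path.
#' @return List of [ratio_estimate()] objects.
#' @export
read_ratio_csv <- function(path) {
  check_header(path, c("zone", "month", "ratio", "sd", "n", "source"))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    ratio_estimate(tab$zone[i], tab$month[i], tab$ratio[i], tab$sd[i],
                   n = tab$n[i], source = tab$source[i])
  })
}
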