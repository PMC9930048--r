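# Episodic dust attribution: contribution of long-range mineral dust
# (e.g. Saharan transport) to annual ambient PM2.5 and to the
# attributable burden.

#' Validate a monthly dust-PM2.5 table
#'
#' @param dust data.frame with columns `zone`, `year`, `month`,
#'   `dust_pm25` (monthly mean dust-PM2.5, ug/m3, >= 0). Months must be
#'   unique within a zone.
#' @return The validated data.frame.
#' @export
as_dust_series <- function(dust) {
  stopifnot(is.data.frame(dust))
  need <- c("zone", "year", "month", "dust_pm25")
  miss <- setdiff(need, names(dust))
  if (length(miss) > 0L) stop("dust series lacks column(s): ", paste(miss, collapse = ", "))
  stopifnot(all(dust$month >= 1), all(dust$month <= 12),
            all(dust$dust_pm25 >= 0))
  key <- paste(dust$zone, dust$year, dust$month)
  if (anyDuplicated(key)) stop("duplicate (zone, year, month) in dust series")
  dust
}

#' Flag dust-episode months
#'
#' @param dust Monthly dust table (see [as_dust_series()]).
#' @param threshold Episode threshold in ug/m3 (>= 0); a month is an
#'   episode iff its dust-PM2.5 strictly exceeds it. Default 0: any
#'   positive dust counts.
#' @return Logical vector aligned to the rows of `dust`.
#' @export
episode_mask <- function(dust, threshold = 0) {
  stopifnot(threshold >= 0)
  dust <- as_dust_series(dust)
  dust$dust_pm25 > threshold
}

#' Annual dust contribution to ambient PM2.5
#'
#' The absolute contribution is the mean monthly dust-PM2.5 over the
#' 12 months of the year (months absent from the table contribute 0);
#' the relative contribution expresses it against a stated ambient
#' annual mean — the denominator is always explicit, never inferred.
#'
#' @param dust Monthly dust table for one zone.
#' @param ambient_annual_mean Ambient annual mean (ug/m3, > 0) used as
#'   the denominator of the relative increase.
#' @param year Calendar year.
#' @return List `abs` (ug/m3) and `rel` (percent).
#' @export
annual_dust_increase <- function(dust, ambient_annual_mean, year) {
  if (ambient_annual_mean <= 0) stop("ambient annual mean must be > 0")
  dust <- as_dust_series(dust)
  dust <- dust[dust$year == year, , drop = FALSE]
  abs_contrib <- sum(dust$dust_pm25) / 12
  list(abs = abs_contrib, rel = 100 * abs_contrib / ambient_annual_mean)
}

#' Share of the attributable burden due to dust
#'
#' Compares two burden results computed from the same configuration
#' except that the counterfactual run removes the dust contribution
#' from ambient PM2.5: `100 * (cases_with - cases_without) /
#' cases_with`, nonnegative whenever dust adds exposure.
#'
#' @param burden_with_dust,burden_without_dust One-row `burden_result`
#'   data.frames sharing endpoint, zone and year.
#' @return Percent of excess cases attributable to dust.
#' @export
dust_burden_share <- function(burden_with_dust, burden_without_dust) {
  for (f in c("endpoint", "zone", "year")) {
    if (!identical(burden_with_dust[[f]], burden_without_dust[[f]])) {
      stop("burden results disagree on ", f, ": ",
           burden_with_dust[[f]], " vs ", burden_without_dust[[f]])
    }
  }
  cw <- burden_with_dust$cases_central
  co <- burden_without_dust$cases_central
  if (cw == 0) return(0)
  100 * (cw - co) / cw
}
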