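# PM2.5 estimation from PM10 through PM2.5/PM10 ratios.
#
# Where no PM2.5 monitor runs, the fine fraction is reconstructed from
# co-located (or zone-level) PM2.5/PM10 ratios. Measured ratios can be
# combined with prior-study values by inverse-variance weighting.

#' Construct a ratio estimate
#'
#' @param zone Zone label, or `"all"` for a global ratio.
#' @param month Calendar month 1-12, or `"all"` for a zone-level ratio.
#' @param ratio Mean PM2.5/PM10 quotient, in (0, 1].
#' @param sd Sample standard deviation of the quotients (>= 0).
#' @param n Number of paired observations behind the estimate.
#' @param source `"measured"`, `"prior"` or `"combined"`.
#' @param n_excluded Pairs discarded because PM2.5 > PM10.
#' @return Object of class `ratio_estimate` (a named list).
#' @export
ratio_estimate <- function(zone, month, ratio, sd, n,
                           source = c("measured", "prior", "combined"),
                           n_excluded = 0L) {
  source <- match.arg(source)
  stopifnot(ratio > 0, ratio <= 1, sd >= 0)
  if (source == "measured") stopifnot(n >= 1)
  structure(list(zone = zone, month = month, ratio = ratio, sd = sd,
                 n = as.integer(n), source = source,
                 n_excluded = as.integer(n_excluded)),
            class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("PM2.5/PM10 ratio [%s, month %s]: %.3f (sd %.3f, n=%d, %s)\n",
              x$zone, as.character(x$month), x$ratio, x$sd, x$n, x$source))
  if (x$n_excluded > 0L) {
    cat(sprintf("  %d pair(s) excluded (PM2.5 > PM10)\n", x$n_excluded))
  }
  invisible(x)
}

#' Monthly PM2.5/PM10 ratio from paired measurements
#'
#' The ratio is the mean of the daily quotients PM2.5/PM10 (not the
#' ratio of the means), which is robust to uneven sampling within the
#' month. Pairs with PM2.5 exceeding PM10 are physically inadmissible
#' for a mass fraction; they are excluded and counted.
#'
#' @param pm25,pm10 Numeric vectors of co-located daily means, paired
#'   by date; `pm10` must be strictly positive for every used pair.
#' @param zone,month Labels carried into the estimate.
#' @return [ratio_estimate()] with `source = "measured"`.
#' @export
monthly_ratio <- function(pm25, pm10, zone, month) {
  stopifnot(length(pm25) == length(pm10))
  keep <- !is.na(pm25) & !is.na(pm10)
  pm25 <- pm25[keep]; pm10 <- pm10[keep]
  if (any(pm10 <= 0)) stop("PM10 must be > 0 in every pair used for a ratio")
  adm <- pm25 <= pm10
  n_excl <- sum(!adm)
  q <- pm25[adm] / pm10[adm]
  if (length(q) < 3L) {
    stop(sprintf("fewer than 3 usable PM2.5/PM10 pairs for zone %s, month %s",
                 zone, as.character(month)))
  }
  ratio_estimate(zone, month, mean(q), stats::sd(q), length(q),
                 source = "measured", n_excluded = n_excl)
}

#' Combine a measured ratio with a prior-study ratio
#'
#' Inverse-variance weighted mean: with variances v1, v2 the combined
#' mean weights each input by 1/v and the combined variance is
#' 1/(1/v1 + 1/v2), which never exceeds the smaller input variance.
#'
#' @param measured,prior [ratio_estimate()] objects with `sd > 0`.
#' @return Combined [ratio_estimate()] (`source = "combined"`). A zero
#'   `sd` on either side is an error: supply an explicit variance floor
#'   instead of an infinitely confident input.
#' @export
combine_ratio_with_prior <- function(measured, prior) {
  stopifnot(inherits(measured, "ratio_estimate"), inherits(prior, "ratio_estimate"))
  if (measured$sd <= 0 || prior$sd <= 0) {
    stop("combine_ratio_with_prior needs sd > 0 on both inputs; ",
         "set an explicit variance floor for degenerate estimates")
  }
  w1 <- 1 / measured$sd^2
  w2 <- 1 / prior$sd^2
  ratio_estimate(measured$zone, measured$month,
                 (w1 * measured$ratio + w2 * prior$ratio) / (w1 + w2),
                 sqrt(1 / (w1 + w2)),
                 n = measured$n + prior$n,
                 source = "combined")
}

#' Look up a ratio with month -> zone -> global fall-back
#'
#' @param ratios List of [ratio_estimate()] objects.
#' @param zone,month Requested zone and month.
#' @param quiet Suppress the fall-back message.
#' @return The most specific matching estimate.
#' @keywords internal
lookup_ratio <- function(ratios, zone, month, quiet = FALSE) {
  pick <- function(z, m) {
    hit <- Filter(function(r) identical(r$zone, z) &&
                    identical(as.character(r$month), as.character(m)), ratios)
    if (length(hit) > 0L) hit[[1L]] else NULL
  }
  r <- pick(zone, month)
  if (is.null(r)) {
    r <- pick(zone, "all")
    if (!is.null(r) && !quiet) {
      message(sprintf("no month-%s ratio for zone %s; falling back to zone-level ratio",
                      as.character(month), zone))
    }
  }
  if (is.null(r)) {
    r <- pick("all", "all")
    if (!is.null(r) && !quiet) {
      message(sprintf("no ratio for zone %s; falling back to global ratio", zone))
    }
  }
  if (is.null(r)) stop("no PM2.5/PM10 ratio available for zone ", zone)
  r
}

#' Annual PM2.5 estimate from annual/monthly PM10 and ratios
#'
#' With monthly summaries, the annual PM2.5 mean is the sum over months
#' of (monthly PM10 mean x monthly ratio), weighted by the number of
#' valid samples in the month — algebraically identical to applying
#' each month's ratio to every valid daily record and averaging.
#' Without monthly detail it degenerates to annual mean x zone ratio.
#'
#' @param pm10_annual One-row [annual_summary()] output; must have
#'   `is_valid = TRUE`.
#' @param ratios List of [ratio_estimate()] objects (see
#'   [lookup_ratio()] for the month -> zone -> global fall-back).
#' @param monthly Optional data.frame of [monthly_summary()] rows for
#'   the same zone-year.
#' @param quiet Suppress fall-back messages.
#' @return List with `pm25` (ug/m3), `sd` (first-order propagated:
#'   relative variances of the PM10 mean and the ratio add), `zone`,
#'   `year`.
#' @export
estimate_pm25_annual <- function(pm10_annual, ratios, monthly = NULL,
                                 quiet = FALSE) {
  stopifnot(is.data.frame(pm10_annual), nrow(pm10_annual) == 1L)
  if (!isTRUE(pm10_annual$is_valid)) {
    stop(sprintf("annual PM10 summary for %s/%d is not valid (n_valid=%d); refusing to estimate PM2.5",
                 pm10_annual$zone, pm10_annual$year, pm10_annual$n_valid))
  }
  zone <- pm10_annual$zone
  if (!is.null(monthly) && nrow(monthly) > 0L) {
    monthly <- monthly[monthly$n_valid > 0L, , drop = FALSE]
    rs <- lapply(monthly$month, function(m) lookup_ratio(ratios, zone, m, quiet))
    rvec <- vapply(rs, `[[`, numeric(1L), "ratio")
    w <- monthly$n_valid
    pm25 <- sum(monthly$mean * rvec * w) / sum(w)
    # effective ratio for first-order sd propagation
    r_eff <- pm25 / (sum(monthly$mean * w) / sum(w))
    r_sd <- sqrt(sum((vapply(rs, `[[`, numeric(1L), "sd") * w)^2)) / sum(w)
  } else {
    r <- lookup_ratio(ratios, zone, "all", quiet)
    pm25 <- pm10_annual$mean * r$ratio
    r_eff <- r$ratio
    r_sd <- r$sd
  }
  mean_se <- if (pm10_annual$n_valid > 0) pm10_annual$sd / sqrt(pm10_annual$n_valid) else NA_real_
  rel_var <- (mean_se / pm10_annual$mean)^2 + (r_sd / r_eff)^2
  list(zone = zone, year = pm10_annual$year,
       pm25 = pm25, sd = pm25 * sqrt(rel_var))
}
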