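# Attributable-burden engine: concentration-response scaling, the
# attributable proportion
#   AP = sum((RR - 1) * P) / sum(RR * P)
# over the exposure distribution, attributable incidence IE = I * AP,
# excess cases NE = IE * N / 100000, confidence-interval propagation
# through the RR bounds, and regional roll-up of zone results.

#' Concentration-response specification
#'
#' A relative risk per 10 ug/m3 with its 95% CI, the pollutant it
#' applies to, the counterfactual cutoff below which no excess risk is
#' attributed, and the functional form used to scale it to an observed
#' concentration.
#'
#' @param endpoint Health endpoint label (e.g. "lung cancer mortality").
#' @param pollutant `"PM10"` or `"PM2.5"`.
#' @param rr,rr_low,rr_high Relative risk per 10 ug/m3 and its 95% CI
#'   bounds; must satisfy `0 < rr_low <= rr <= rr_high`.
#' @param cutoff Counterfactual concentration (ug/m3, >= 0). Defaults
#'   to the WHO 2021 annual guideline for the pollutant: 15 for PM10,
#'   5 for PM2.5.
#' @param form `"log_linear"` (risk compounds multiplicatively per
#'   10 ug/m3; standard practice) or `"linear"`.
#' @return Object of class `crf`.
#' @examples
#' crf("lung cancer mortality", "PM2.5", 1.11, 1.05, 1.18)
#' @export
crf <- function(endpoint, pollutant = c("PM10", "PM2.5"),
                rr, rr_low = rr, rr_high = rr,
                cutoff = NULL, form = c("log_linear", "linear")) {
  pollutant <- match.arg(pollutant)
  form <- match.arg(form)
  if (is.null(cutoff)) cutoff <- if (pollutant == "PM10") 15 else 5
  stopifnot(rr_low > 0, rr_low <= rr, rr <= rr_high, cutoff >= 0)
  structure(list(endpoint = endpoint, pollutant = pollutant,
                 rr = rr, rr_low = rr_low, rr_high = rr_high,
                 cutoff = cutoff, form = form),
            class = "crf")
}

#' @export
print.crf <- function(x, ...) {
  cat(sprintf("CRF: %s [%s], RR %.4f (%.4f-%.4f) per 10 ug/m3, cutoff %g ug/m3, %s\n",
              x$endpoint, x$pollutant, x$rr, x$rr_low, x$rr_high,
              x$cutoff, x$form))
  invisible(x)
}

#' Exposure distribution over concentration categories
#'
#' The population fractions P of the attributable-proportion formula.
#' A single category at the zone annual mean reproduces the usual
#' zone-year assessment; multiple categories support a binned
#' distribution of daily values.
#'
#' @param conc Category concentrations (ug/m3, >= 0).
#' @param frac Population fractions (>= 0, summing to 1 within 1e-9).
#' @return Object of class `exposure_dist`.
#' @export
exposure_dist <- function(conc, frac = rep(1 / length(conc), length(conc))) {
  stopifnot(length(conc) == length(frac), length(conc) >= 1L,
            all(conc >= 0), all(frac >= 0))
  if (abs(sum(frac) - 1) > 1e-9) {
    stop("population fractions must sum to 1 (got ", format(sum(frac)), ")")
  }
  structure(list(conc = as.numeric(conc), frac = as.numeric(frac)),
            class = "exposure_dist")
}

#' Binned exposure distribution from valid daily values
#'
#' @param pm Numeric vector of valid daily concentrations.
#' @param width Bin width in ug/m3 (default 10); categories are bin
#'   midpoints, fractions the share of days per bin.
#' @return [exposure_dist()].
#' @export
binned_exposure <- function(pm, width = 10) {
  pm <- pm[!is.na(pm)]
  stopifnot(length(pm) >= 1L, width > 0)
  bin <- floor(pm / width)
  tab <- table(bin)
  exposure_dist(conc = (as.numeric(names(tab)) + 0.5) * width,
                frac = as.numeric(tab) / length(pm))
}

#' Scale a per-10-ug/m3 relative risk to a concentration
#'
#' Only exposure above the counterfactual cutoff contributes; at or
#' below the cutoff the relative risk is exactly 1 (no protective
#' extrapolation). With excess d = conc - cutoff, the log-linear form
#' compounds `rr^(d/10)`; the linear form is `1 + (rr - 1) * d / 10`.
#'
#' @param crf [crf()] specification.
#' @param conc Concentration(s), ug/m3, >= 0.
#' @param which CI bound of the RR to use: `"central"`, `"low"`,
#'   `"high"`.
#' @return Relative risk(s), always > 0, vectorised over `conc`.
#' @export
scale_rr <- function(crf, conc, which = c("central", "low", "high")) {
  stopifnot(inherits(crf, "crf"), all(conc >= 0))
  which <- match.arg(which)
  rr10 <- switch(which, central = crf$rr, low = crf$rr_low, high = crf$rr_high)
  d <- pmax(conc - crf$cutoff, 0)
  if (crf$form == "log_linear") rr10^(d / 10) else 1 + (rr10 - 1) * d / 10
}

#' Attributable proportion of a health outcome
#'
#' `AP = sum((RR(c) - 1) * P(c)) / sum(RR(c) * P(c))` over the exposure
#' categories, with RR(c) from [scale_rr()] at the selected CI bound.
#' For RR >= 1 the result lies in \[0, 1); for a point-mass
#' distribution it reduces to (RR - 1)/RR.
#'
#' @param dist [exposure_dist()].
#' @inheritParams scale_rr
#' @return Proportion (dimensionless, not percent).
#' @export
attributable_proportion <- function(dist, crf,
                                    which = c("central", "low", "high")) {
  stopifnot(inherits(dist, "exposure_dist"))
  which <- match.arg(which)
  rr <- scale_rr(crf, dist$conc, which)
  sum((rr - 1) * dist$frac) / sum(rr * dist$frac)
}

#' Attributable incidence IE = I x AP
#'
#' @param incidence Baseline incidence, cases per 100,000 per year.
#' @param ap Attributable proportion in \[0, 1).
#' @return Attributable cases per 100,000 per year.
#' @export
attributable_incidence <- function(incidence, ap) {
  stopifnot(incidence >= 0, ap >= 0, ap < 1)
  incidence * ap
}

#' Population group at risk
#'
#' @param zone Zone label.
#' @param count Resident population count.
#' @param representativeness Share of the population whose exposure the
#'   monitoring network represents, in (0, 1]; scales the effective
#'   population at risk.
#' @param age_band Optional label (e.g. "0-4", ">18").
#' @return Object of class `population_group`.
#' @export
population_group <- function(zone, count, representativeness = 1,
                             age_band = "all") {
  stopifnot(count >= 0, representativeness > 0, representativeness <= 1)
  structure(list(zone = zone, count = count,
                 representativeness = representativeness,
                 age_band = age_band),
            class = "population_group")
}

#' Effective population at risk
#' @param pop [population_group()].
#' @return `count * representativeness`.
#' @export
effective_population <- function(pop) {
  stopifnot(inherits(pop, "population_group"))
  pop$count * pop$representativeness
}

#' Excess cases NE = IE x N / 100,000
#'
#' @param ie Attributable incidence (cases per 100,000 per year).
#' @param pop [population_group()]; the effective population is
#'   `count * representativeness`.
#' @return Expected excess cases per year, unrounded (display rounding
#'   belongs to report serialization, never to computation).
#' @export
attributable_cases <- function(ie, pop) {
  stopifnot(ie >= 0)
  ie * effective_population(pop) / 1e5
}

#' Excess-case rate per 100,000 at risk
#'
#' Algebraic inverse of [attributable_cases()]: recovers the
#' attributable incidence from a case count.
#'
#' @param ne Excess cases per year.
#' @param pop [population_group()] with effective population > 0.
#' @return Cases per 100,000 per year.
#' @export
cases_per_100k <- function(ne, pop) {
  np <- effective_population(pop)
  if (np <= 0) stop("effective population must be > 0")
  ne / np * 1e5
}

#' Burden estimate with CI propagation through the RR bounds
#'
#' Runs the AP -> IE -> NE chain three times, at the low, central and
#' high relative risk. Baseline incidence and population are treated as
#' fixed (the concentration-response function is the only input whose
#' uncertainty is quantified by a CI).
#'
#' @param dist [exposure_dist()].
#' @param crf [crf()].
#' @param incidence Baseline incidence, cases per 100,000 per year.
#' @param pop [population_group()].
#' @param zone,year Metadata carried into the result; `zone` defaults
#'   to the population group's zone.
#' @return One-row data.frame of class `burden_result` with columns
#'   `endpoint`, `zone`, `year`, `ap_low/central/high` (proportions),
#'   `cases_low/central/high` (persons/year) and `rate_per_100k`
#'   (central excess cases per 100,000 effective population).
#' @export
burden_with_ci <- function(dist, crf, incidence, pop,
                           zone = pop$zone, year = NA_integer_) {
  one <- function(which) {
    ap <- attributable_proportion(dist, crf, which)
    ne <- attributable_cases(attributable_incidence(incidence, ap), pop)
    c(ap = ap, ne = ne)
  }
  lo <- one("low"); ce <- one("central"); hi <- one("high")
  out <- data.frame(endpoint = crf$endpoint, zone = zone,
                    year = as.integer(year),
                    ap_low = lo["ap"], ap_central = ce["ap"], ap_high = hi["ap"],
                    cases_low = lo["ne"], cases_central = ce["ne"],
                    cases_high = hi["ne"],
                    rate_per_100k = cases_per_100k(ce["ne"], pop),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("burden_result", class(out))
  out
}

#' Assemble a burden row from already-known quantities
#'
#' Used to ingest published zone-level results (attributable proportion
#' and excess cases) so they can be rolled up or compared.
#'
#' @param endpoint,zone,year Metadata.
#' @param cases_central Excess cases per year (central).
#' @param ap_central Attributable proportion (central), as a proportion.
#' @param cases_low,cases_high,ap_low,ap_high Optional bounds (default
#'   the central values).
#' @param rate_per_100k Optional rate (default `NA`).
#' @return One-row `burden_result` data.frame.
#' @export
burden_row <- function(endpoint, zone, year, cases_central, ap_central = NA_real_,
                       cases_low = cases_central, cases_high = cases_central,
                       ap_low = ap_central, ap_high = ap_central,
                       rate_per_100k = NA_real_) {
  out <- data.frame(endpoint = endpoint, zone = zone, year = as.integer(year),
                    ap_low = ap_low, ap_central = ap_central, ap_high = ap_high,
                    cases_low = cases_low, cases_central = cases_central,
                    cases_high = cases_high, rate_per_100k = rate_per_100k,
                    stringsAsFactors = FALSE)
  class(out) <- c("burden_result", class(out))
  out
}

#' Roll zone burdens up to the region
#'
#' Regional excess cases are the sum of the zone cases, bound by bound;
#' the regional attributable proportion is the effective-population-
#' weighted mean of the zone proportions; the regional rate is total
#' cases over total effective population, per 100,000.
#'
#' @param zone_results `burden_result` data.frame (one row per zone),
#'   sharing one endpoint and year.
#' @param zone_pops List of [population_group()], one per row of
#'   `zone_results` (matched by zone label). May be omitted when only
#'   case totals are needed; AP and rate are then `NA`.
#' @return One-row `burden_result` with `zone = "region"`.
#' @export
regional_rollup <- function(zone_results, zone_pops = NULL) {
  stopifnot(inherits(zone_results, "data.frame"), nrow(zone_results) >= 1L)
  if (length(unique(zone_results$endpoint)) != 1L) {
    stop("regional roll-up across different endpoints: ",
         paste(unique(zone_results$endpoint), collapse = ", "))
  }
  yrs <- unique(zone_results$year[!is.na(zone_results$year)])
  if (length(yrs) > 1L) {
    stop("regional roll-up across different years: ", paste(yrs, collapse = ", "))
  }
  cases <- vapply(c("cases_low", "cases_central", "cases_high"),
                  function(cl) sum(zone_results[[cl]]), numeric(1L))
  if (!is.null(zone_pops)) {
    idx <- match(zone_results$zone,
                 vapply(zone_pops, `[[`, character(1L), "zone"))
    if (anyNA(idx)) stop("no population group for zone(s): ",
                         paste(zone_results$zone[is.na(idx)], collapse = ", "))
    npe <- vapply(zone_pops[idx], effective_population, numeric(1L))
    w <- npe / sum(npe)
    ap <- vapply(c("ap_low", "ap_central", "ap_high"),
                 function(cl) sum(zone_results[[cl]] * w), numeric(1L))
    rate <- cases[["cases_central"]] / sum(npe) * 1e5
  } else {
    ap <- c(ap_low = NA_real_, ap_central = NA_real_, ap_high = NA_real_)
    rate <- NA_real_
  }
  burden_row(endpoint = zone_results$endpoint[1L], zone = "region",
             year = if (length(yrs) == 1L) yrs else NA_integer_,
             cases_central = cases[["cases_central"]],
             cases_low = cases[["cases_low"]],
             cases_high = cases[["cases_high"]],
             ap_central = ap[["ap_central"]], ap_low = ap[["ap_low"]],
             ap_high = ap[["ap_high"]], rate_per_100k = rate)
}

#' @export
print.burden_result <- function(x, digits = 3, ...) {
  cat(sprintf("Attributable burden (%d row%s):\n", nrow(x),
              if (nrow(x) == 1L) "" else "s"))
  df <- as.data.frame(x)
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}
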