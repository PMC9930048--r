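# Packaged study configuration: concentration-response functions,
# baseline incidences, population at risk, PM2.5/PM10 ratio priors,
# the published annual PM10 means, and the published zone-level burden
# tables used for roll-up checks.
#
# Zone population counts are a synthetic 45/30/25% split of the
# regional total (the census reports only the regional total and its
# age structure); the split is flagged in the fixture file itself.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "pmhia")
  if (p == "") stop("fixture not found: ", file)
  p
}

#' Packaged study configuration tables
#'
#' Loads and validates the shipped configuration: the
#' concentration-response table (relative risks per 10 ug/m3 with 95%
#' CIs and WHO-2021 cutoffs of 15 ug/m3 PM10 / 5 ug/m3 PM2.5),
#' zone baseline incidences, population at risk (regional total
#' 880,560; age structure 22.6% / 68.3% / 9.1% for 0-14 / 15-64 / 65+;
#' monitoring representativeness 58.1% / 69.3% / 63.8% for
#' coastal/industrial/mountainous; a synthetic zone split), zone-level
#' PM2.5/PM10 ratio priors (0.5 +/- 0.3 industrial, 0.4 +/- 0.2
#' elsewhere), the published annual PM10 zone means, published
#' zone-level burden tables for two morbidity endpoints, and study-wide
#' attributable-death totals.
#'
#' @return Named list of data.frames: `crf`, `incidence`, `population`,
#'   `age_bands`, `ratio_priors`, `annual_pm10`, `bronchitis_children`,
#'   `chronic_bronchitis_adults`, `study_totals`.
#' @export
fixture_tables <- function() {
  crf_tab <- utils::read.csv(fixture_path("crf_table.csv"),
                             stringsAsFactors = FALSE)
  stopifnot(all(crf_tab$rr_low <= crf_tab$rr_central),
            all(crf_tab$rr_central <= crf_tab$rr_high),
            all(crf_tab$rr_low > 0), all(crf_tab$cutoff >= 0))
  pop <- utils::read.csv(fixture_path("population_table.csv"),
                         stringsAsFactors = FALSE)
  stopifnot(all(pop$count >= 0), all(pop$representativeness > 0),
            all(pop$representativeness <= 1))
  age <- utils::read.csv(fixture_path("age_bands.csv"),
                         stringsAsFactors = FALSE)
  stopifnot(abs(sum(age$fraction) - 1) < 1e-9)
  list(crf = crf_tab,
       incidence = utils::read.csv(fixture_path("incidence_table.csv"),
                                   stringsAsFactors = FALSE),
       population = pop,
       age_bands = age,
       ratio_priors = utils::read.csv(fixture_path("ratio_priors.csv"),
                                      stringsAsFactors = FALSE),
       annual_pm10 = utils::read.csv(fixture_path("annual_pm10.csv"),
                                     stringsAsFactors = FALSE),
       bronchitis_children = utils::read.csv(
         fixture_path("bronchitis_children_burden.csv"),
         stringsAsFactors = FALSE),
       chronic_bronchitis_adults = utils::read.csv(
         fixture_path("chronic_bronchitis_adults_burden.csv"),
         stringsAsFactors = FALSE),
       study_totals = utils::read.csv(fixture_path("study_totals.csv"),
                                      stringsAsFactors = FALSE))
}

#' Look up a packaged concentration-response function
#'
#' @param endpoint Endpoint label as in the fixture table.
#' @param pollutant `"PM10"` or `"PM2.5"`.
#' @param tables Optional pre-loaded [fixture_tables()].
#' @return A [crf()] object.
#' @export
fixture_crf <- function(endpoint, pollutant, tables = fixture_tables()) {
  tab <- tables$crf
  row <- tab[tab$endpoint == endpoint & tab$pollutant == pollutant, ]
  if (nrow(row) != 1L) {
    stop("no unique CRF for endpoint '", endpoint, "' and pollutant ", pollutant)
  }
  crf(endpoint, pollutant, row$rr_central, row$rr_low, row$rr_high,
      cutoff = row$cutoff, form = row$form)
}

#' Packaged population group for a zone
#'
#' @param zone Zone label.
#' @param group Age selection: `"all"`, `"children"` (the 0-14 band)
#'   or `"adults"` (15+). The published adult analyses cover people
#'   over 18; census bands resolve only to 0-14 / 15-64 / 65+, so the
#'   15+ share is the closest available stand-in and the selection is
#'   an explicit argument rather than a buried assumption.
#' @param tables Optional pre-loaded [fixture_tables()].
#' @return A [population_group()].
#' @export
fixture_population <- function(zone, group = c("all", "children", "adults"),
                               tables = fixture_tables()) {
  group <- match.arg(group)
  pop <- tables$population
  row <- pop[pop$zone == zone, ]
  if (nrow(row) != 1L) stop("no population fixture for zone ", zone)
  age <- tables$age_bands
  frac <- switch(group,
                 all = 1,
                 children = age$fraction[age$age_band == "0-14"],
                 adults = sum(age$fraction[age$age_band %in% c("15-64", "65+")]))
  population_group(zone, row$count * frac, row$representativeness,
                   age_band = group)
}

#' Packaged zone-level ratio priors as estimates
#'
#' @param tables Optional pre-loaded [fixture_tables()].
#' @return List of [ratio_estimate()] objects (`source = "prior"`).
#' @export
fixture_ratio_priors <- function(tables = fixture_tables()) {
  tab <- tables$ratio_priors
  lapply(seq_len(nrow(tab)), function(i) {
    ratio_estimate(tab$zone[i], tab$month[i], tab$ratio[i], tab$sd[i],
                   n = max(tab$n[i], 0L), source = "prior")
  })
}
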