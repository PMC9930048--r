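# Attributable-burden engine: RR scaling, AP, IE/NE chain, roll-up.

test_that("relative risk scaling honours the cutoff and the 10 ug/m3 unit", {
  lc <- crf("lung cancer mortality", "PM2.5", 1.11, 1.05, 1.18)  # cutoff 5
  expect_equal(scale_rr(lc, lc$cutoff + 10), 1.11)
  lin <- crf("lung cancer mortality", "PM2.5", 1.11, form = "linear")
  expect_equal(scale_rr(lin, lin$cutoff + 10), 1.11)
  expect_equal(scale_rr(lc, lc$cutoff), 1)
  expect_equal(scale_rr(lc, 0), 1)          # below cutoff: never protective
  expect_equal(scale_rr(lc, lc$cutoff + 20), 1.11^2)  # compounding
  expect_equal(scale_rr(lin, lin$cutoff + 20), 1.22)  # linear accumulation
  expect_equal(scale_rr(lc, lc$cutoff + 10, "low"), 1.05)
  expect_equal(scale_rr(lc, lc$cutoff + 10, "high"), 1.18)
})

test_that("attributable proportion matches closed forms", {
  lc <- crf("lung cancer mortality", "PM2.5", 1.11, 1.05, 1.18)
  # point mass at cutoff + 10: AP = (RR-1)/RR
  expect_equal(attributable_proportion(exposure_dist(15, 1), lc),
               0.11 / 1.11)
  # everything at or below the cutoff: nothing attributable
  expect_equal(attributable_proportion(exposure_dist(c(2, 5), c(0.5, 0.5)), lc), 0)
  # two categories with RR 1.0 and 1.2 at half weight each: 0.1/1.1
  r12 <- crf("x", "PM10", 1.2, cutoff = 15)
  d2 <- exposure_dist(c(15, 25), c(0.5, 0.5))
  expect_equal(attributable_proportion(d2, r12), 0.1 / 1.1)
})

test_that("pipeline AP equals the brute-force loop on random distributions", {
  set.seed(61)
  for (i in 1:200) {
    k <- sample(1:20, 1)
    conc <- runif(k, 0, 120)
    frac <- rgamma(k, 1); frac <- frac / sum(frac)
    rr10 <- runif(1, 1, 1.3)
    cutoff <- runif(1, 0, 30)
    form <- sample(c("log_linear", "linear"), 1)
    cr <- crf("x", "PM10", rr10, cutoff = cutoff, form = form)
    expect_equal(attributable_proportion(exposure_dist(conc, frac), cr),
                 ap_brute_force(conc, frac, rr10, cutoff, form),
                 tolerance = 1e-12)
  }
})

test_that("AP is monotone in concentration and in the relative risk", {
  set.seed(62)
  cr <- crf("x", "PM10", 1.05)
  d <- exposure_dist(c(20, 40, 60), c(0.2, 0.5, 0.3))
  ap0 <- attributable_proportion(d, cr)
  d_up <- exposure_dist(c(25, 40, 60), c(0.2, 0.5, 0.3))
  expect_gte(attributable_proportion(d_up, cr), ap0)
  expect_gte(attributable_proportion(d, crf("x", "PM10", 1.08)), ap0)
})

test_that("linear and log-linear APs agree to first order in the excess risk", {
  # both forms coincide at the cutoff and at cutoff + 10; in between the
  # gap is second order in (RR - 1), so quartering the excess risk when
  # it is halved
  dgrid <- seq(0.25, 9.75, by = 0.5)
  max_gap <- function(rr10) {
    cll <- crf("x", "PM10", rr10, cutoff = 15, form = "log_linear")
    cli <- crf("x", "PM10", rr10, cutoff = 15, form = "linear")
    max(vapply(dgrid, function(d) {
      dd <- exposure_dist(15 + d, 1)
      abs(attributable_proportion(dd, cll) - attributable_proportion(dd, cli))
    }, numeric(1)))
  }
  g2 <- max_gap(1.2); g1 <- max_gap(1.1); g05 <- max_gap(1.05)
  expect_lt(g1, g2 / 3)       # ~ quarter when (RR-1) halves
  expect_lt(g05, g1 / 3)
  expect_lt(g1, (0.1)^2)      # gap bounded by (RR-1)^2 scale
})

test_that("incidence, case and rate arithmetic is exact and invertible", {
  expect_equal(attributable_incidence(4.91, 0.10), 0.491)
  expect_equal(attributable_incidence(4.91, 0), 0)
  expect_equal(attributable_incidence(0, 0.5), 0)
  pop1 <- population_group("industrial", 1e5, 1)
  expect_equal(attributable_cases(0.491, pop1), 0.491)
  pop_rep <- population_group("industrial", 1e5, 0.693)
  expect_equal(attributable_cases(0.491, pop_rep), 0.491 * 0.693)
  expect_equal(attributable_cases(0.5, population_group("c", 0, 1)), 0)
  # cases_per_100k inverts attributable_cases
  ne <- attributable_cases(0.491, pop_rep)
  expect_equal(cases_per_100k(ne, pop_rep), 0.491, tolerance = 1e-12)
  expect_equal(cases_per_100k(24, population_group("c", 1e5, 1)), 24)
  # doubling the population halves the rate at fixed case count
  expect_equal(cases_per_100k(24, population_group("c", 2e5, 1)), 12)
})

test_that("burden_with_ci composes the chain and orders the bounds", {
  lc <- crf("lung cancer mortality", "PM2.5", 1.11, 1.05, 1.18)
  d <- exposure_dist(c(12, 22), c(0.4, 0.6))
  pop <- population_group("industrial", 264168, 0.693)
  b <- burden_with_ci(d, lc, 4.91, pop, year = 2015)
  expect_true(b$ap_low < b$ap_central && b$ap_central < b$ap_high)
  expect_true(b$cases_low < b$cases_central && b$cases_central < b$cases_high)
  # composition oracle: recompute each bound by explicit chaining
  for (w in c("low", "central", "high")) {
    ap <- attributable_proportion(d, lc, w)
    ne <- attributable_cases(attributable_incidence(4.91, ap), pop)
    expect_equal(b[[paste0("ap_", w)]], ap, tolerance = 1e-12)
    expect_equal(b[[paste0("cases_", w)]], ne, tolerance = 1e-12)
  }
  expect_equal(b$rate_per_100k, cases_per_100k(b$cases_central, pop),
               tolerance = 1e-12)
  # degenerate CI: all three bounds coincide
  flat <- crf("x", "PM10", 1.05, 1.05, 1.05)
  bf <- burden_with_ci(d, flat, 10, pop)
  expect_equal(bf$ap_low, bf$ap_high)
  expect_equal(bf$cases_low, bf$cases_high)
})

test_that("no exposure above the cutoff means zero burden end to end", {
  cr <- crf("x", "PM10", 1.2, cutoff = 15)
  d <- exposure_dist(c(5, 10, 15), c(0.3, 0.3, 0.4))
  b <- burden_with_ci(d, cr, 50, population_group("c", 1e5, 1))
  expect_equal(b$ap_central, 0)
  expect_equal(b$cases_central, 0)
})

test_that("regional roll-up sums cases and weights AP by population", {
  rows <- rbind(burden_row("b", "coastal", 2011, 12, 0.05),
                burden_row("b", "industrial", 2011, 13, 0.157),
                burden_row("b", "mountainous", 2011, 16, 0.086))
  expect_equal(regional_rollup(rows)$cases_central, 41)
  pops <- list(population_group("coastal", 100, 1),
               population_group("industrial", 100, 1),
               population_group("mountainous", 200, 1))
  reg <- regional_rollup(rows, pops)
  expect_equal(reg$ap_central, (0.05 * 100 + 0.157 * 100 + 0.086 * 200) / 400)
  expect_equal(reg$rate_per_100k, 41 / 400 * 1e5)
  # single zone: identity on cases
  expect_equal(regional_rollup(rows[1, ])$cases_central, 12)
  # conservation holds bound by bound for computed burdens
  lc <- crf("lung cancer mortality", "PM2.5", 1.11, 1.05, 1.18)
  zb <- do.call(rbind, lapply(c(18, 22, 15), function(m)
    burden_with_ci(exposure_dist(m, 1), lc, 4.91,
                   population_group("coastal", 1e5, 0.6), year = 2015)))
  zb$zone <- pm_zones()
  reg2 <- regional_rollup(zb)
  for (cl in c("cases_low", "cases_central", "cases_high")) {
    expect_equal(reg2[[cl]], sum(zb[[cl]]), tolerance = 0)
  }
  # mixed metadata is refused
  mixed <- rows; mixed$endpoint[2] <- "other"
  expect_error(regional_rollup(mixed), "endpoint")
  wrong_year <- rows; wrong_year$year[3] <- 2012L
  expect_error(regional_rollup(wrong_year), "year")
})

test_that("binned exposure distributions are valid and centred on the data", {
  set.seed(63)
  pm <- rlnorm(500, log(35), 0.3)
  d <- binned_exposure(pm)
  expect_equal(sum(d$frac), 1, tolerance = 1e-12)
  expect_true(all(d$conc >= 0))
  expect_lt(abs(sum(d$conc * d$frac) - mean(pm)), 5)  # midpoints track the mean
})
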