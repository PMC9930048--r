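# Builders for small in-code fixtures.

make_records <- function(n, zone = "coastal", year = 2015, pm10 = 30,
                         sample_hours = 24, reject_flag = "none",
                         station_id = "s1") {
  data.frame(station_id = rep_len(station_id, n), zone = rep_len(zone, n),
             date = seq(as.Date(sprintf("%d-01-01", year)), by = "3 days",
                        length.out = n),
             pm10 = rep_len(pm10, n),
             sample_hours = rep_len(sample_hours, n),
             reject_flag = rep_len(reject_flag, n),
             stringsAsFactors = FALSE)
}

# brute-force attributable proportion: explicit loop over categories,
# independent of the vectorised pipeline implementation
ap_brute_force <- function(conc, frac, rr10, cutoff, form = "log_linear",
                           which_rr = rr10) {
  num <- 0; den <- 0
  for (i in seq_along(conc)) {
    d <- max(conc[i] - cutoff, 0)
    rr <- if (form == "log_linear") which_rr^(d / 10) else 1 + (which_rr - 1) * d / 10
    num <- num + (rr - 1) * frac[i]
    den <- den + rr * frac[i]
  }
  num / den
}
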