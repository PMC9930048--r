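Package: pmhia
Title: Health Impact Assessment for Particulate Matter Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the health burden attributable to ambient
    particulate matter (PM10 and PM2.5) from routine monitoring data.
    Implements exposure quality control and completeness accounting for
    daily filter-based PM10 records, PM2.5 estimation through PM2.5/PM10
    ratios with inverse-variance combination of measured and prior ratios,
    attributable-proportion and excess-case estimation from relative risks
    per 10 ug/m3 with counterfactual cutoffs and confidence-interval
    propagation, regional roll-up of zone-level burdens, short-term
    quasi-Poisson time-series regression of daily mortality on PM with
    natural-spline time adjustment and random-effects pooling across zones,
    accounting of episodic desert-dust contributions to annual PM2.5 and to
    the attributable burden, and a fully deterministic synthetic-data
    generator for exposure, dust and daily-mortality series with
    ground-truth bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
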