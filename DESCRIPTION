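Package: sgdflux
Title: Radon-Traced Submarine Groundwater Discharge and Coastal CO2 Fluxes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify when, where and how submarine groundwater
    discharge (SGD) delivers carbon dioxide to shallow coastal waters from
    coupled pCO2 and radon-222 time-series observations. Implements reading,
    alignment and lag correction of equilibrator-based surface-water series;
    gas solubility, Schmidt-number and wind-based gas transfer velocity
    calculations for water-air CO2 and radon fluxes; steady-state, non-steady
    and tidal-cycle-integrated radon mass balances with Monte Carlo
    uncertainty; driver attribution via Pearson correlations, CUSUM
    driver-response curves and tidal/diel effect indices; and two-end-member
    mixing diagnostics (deviation quotient). A synthetic box-model generator
    produces tidally modulated coastal time series with recorded ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
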