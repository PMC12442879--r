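Package: carbniche
Title: Carbonate Chemistry Fitness Landscapes for Phytoplankton Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping phytoplankton fitness across seawater carbonate
    chemistry landscapes. Implements total-scale speciation of the seawater
    carbonate system from any supported input pair (total alkalinity with pH,
    dissolved inorganic carbon, or pCO2), fits optimum-curve growth models
    (Michaelis-Menten with an optional linear inhibition term) to growth versus
    CO2 data with bootstrap confidence intervals, derives half-saturation
    constants and maximum rates, projects fitted models over alkalinity by
    carbon space, and computes ocean acidification and ocean alkalinity
    enhancement scenario trajectories and thresholds. Includes a synthetic
    batch-culture experiment generator for end-to-end testing and power
    analysis, and helpers for harmonizing published growth records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
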