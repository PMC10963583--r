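Package: heatscape
Title: Hourly Metre-Scale Projection of Urban Outdoor Thermal Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for projecting pedestrian-level outdoor
    thermal stress in urban sites at hourly and metre scale. Provides grouped
    quantile delta mapping and an N-dimensional multivariate bias correction
    (MBCn) for the four meteorological drivers of the Universal Thermal
    Climate Index (UTCI); a simplified SOLWEIG-style radiation scheme that
    casts building and canopy shadows on digital surface models, computes sky
    view factors, and derives mean radiant temperature for a cylindrical
    person at 1.5 m; the operational sixth-order UTCI polynomial with stress
    categorisation; and thermal-stress climatology statistics (site-wide
    extremes, hour-by-day-of-year change fields, percentile bands, stress-hour
    accounting, June-to-May cumulative seasons, and summary tables with change
    factors). A seeded synthetic-data module generates reference and biased
    model meteorology with known structure, plus toy urban scenes, so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
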