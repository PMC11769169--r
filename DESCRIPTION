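Package: cellfarm
Title: Cell-Size Analysis of Coffee Farm Yield, Fertilization and Profitability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for the cell-size (small-plot) analysis of perennial coffee
    production. A farm is divided into cells, each represented by one composite
    soil, leaf and yield value per season. The package computes per-cell and
    farm-level biennial-bearing magnitude, phosphate and potassium fertilizer
    recommendations under uniform and localized (per-cell) management using
    nutrient-export coefficients with a soil-availability lookup fallback for
    zero-harvest (skeletonization) years, per-cell revenue, cost and
    profitability by season, and descriptive and correlation screening of soil
    and leaf panels. A seeded synthetic-farm generator with known ground truth
    supports end-to-end testing and parameter-recovery studies without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stats,
    jsonlite,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
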