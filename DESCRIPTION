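Package: pmcrossover
Title: Time-Stratified Case-Crossover Analysis of Short-Term PM2.5 and
    Mortality with Racial Segregation Effect Modifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for time-stratified case-crossover studies of
    short-term fine particulate matter (PM2.5) exposure and daily
    mortality, with effect modification by decedent race, neighborhood
    racial composition, and census-derived residential segregation
    indices. Implements block-group racial concentration (RRS) and
    tract-level racial dissimilarity (IRD) scores, nearest-grid-cell
    exposure assignment with lag/moving-average windows, time-stratified
    referent selection (every third day within the same month and year),
    a Newton-Raphson conditional logistic likelihood maximizer for
    matched sets, percent-change-per-10-ug/m3 effect reporting with
    delta-method confidence intervals at stated modifier values, and a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    geosphere,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
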