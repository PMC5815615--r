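Package: isokrig
Title: Stable-Isotope Isoscapes for Timber Provenance by Kriging and Cokriging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geostatistical construction of tree-ring stable-isotope isoscapes
    (delta-18O, delta-2H) for timber provenance studies. Provides dendrochronological
    cross-dating statistics (Gleichlaeufigkeit, correlation t-value), covariate
    preparation (altitude extraction, canopy cover from a canopy-height model,
    standardization), exploratory spatial statistics (descriptive summaries,
    Pearson screening, AIC covariate ranking, Moran's I with permutation test),
    empirical and directional variograms with spherical, exponential, linear and
    Matern-Stein model fitting, a linear model of coregionalization, ordinary and
    universal kriging and co-located cokriging with exact solvers, leave-one-out
    cross-validation with RMSE and MSDR diagnostics, model ranking, and gridded
    isoscape output with 95 percent confidence surfaces. A synthetic-data module
    generates Alpine-like random fields with known ground truth so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    knitr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
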