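Package: dendrogrowth
Title: Climate-Growth and Growth-Trend Analysis for Treeline Tree-Ring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dendroecological analysis of climate-growth
    relationships at alpine treeline. Reads and writes Tucson/RWL ring-width
    files, detrends series with a wavelength-parametrized smoothing spline or
    regional curve standardization (with geometric pith-offset estimation),
    builds lagged monthly-temperature design matrices, and fits linear
    mixed-effects models with tree-level random effects and AR(1) residual
    correlation from the marginal likelihood. Includes exhaustive BIC subset
    selection over monthly temperature predictors, long-term growth-trend
    models with an elevation interaction, stand-structure summaries from
    canopy height tables, and a synthetic-data generator with recorded ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite
Config/testthat/edition: 3
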