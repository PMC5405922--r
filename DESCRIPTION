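Package: coralkrige
Title: Indicator Kriging of Mass Coral Bleaching Occurrence from Severity-Coded Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for mapping the annual probability of mass coral
    bleaching on a 0.04 degree reef grid. Severity-coded bleaching reports
    (ReefBase-style schema) are quality-filtered and rasterized to presence
    cells; Degree Heating Week (DHW) thermal stress computed from sea surface
    temperature and a maximum-monthly-mean climatology supplies pseudo-absence
    cells (reef cells with zero annual thermal stress); annual bleaching
    probabilities are interpolated per ocean region by ordinary indicator
    kriging, with the semi-variogram model chosen by lowest RMSE among nine
    standard families and the Pacific tiled into overlapping sections whose
    estimates are averaged. Downstream statistics include reef area above
    probability thresholds, area-weighted DHW by probability class, period
    fold changes, Welch tests, and linear trends. A synthetic-data module
    generates reef grids, SST series, latent probability fields, and
    effort-biased reports so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
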