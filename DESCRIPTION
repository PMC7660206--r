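Package: laiseason
Title: Full-Season Green LAI Estimation for Spring Maize by Combining
    Vegetation-Index Regression, Ensemble Kalman Filter Assimilation and a
    Hybrid Free-Run Method
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates daily green leaf area index (LAI) of spring maize over
    the whole growth season by switching between three methods by phenological
    stage: a per-date linear vegetation-index (VI) model early in the season,
    ensemble Kalman filter (EnKF) assimilation of remote-sensing LAI into a
    reduced-order daily crop growth simulator during the rainy mid season, and
    a hybrid method that halts assimilation at tasseling (DVS = 1) and lets
    the crop model free-run to maturity, where reflectance saturation and leaf
    senescence corrupt optical retrievals. Includes the five vegetation index
    definitions (NDVI, RVI, OSAVI, EVI2, MTVI2), a gain-inflation guard
    against filter divergence, per-campaign calibration with averaging of
    per-date optima, inverse-distance temporal interpolation, evaluation
    statistics (R, fitted-line R2, RMSE, CV), and a synthetic scene generator
    (weather, soil nutrients, true LAI, five-band reflectance with saturation
    and senescence, noisy field campaigns) so the full workflow runs end to
    end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
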