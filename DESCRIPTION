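Package: vhicast
Title: Vegetation Health Index Forecasting with Convolutional LSTM Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the Vegetation Condition Index (VCI), Thermal Condition
    Index (TCI) and Vegetation Health Index (VHI) from NDVI and land surface
    temperature raster time series under image-based or global-scale min-max
    normalization, aligns daily imagery to the MODIS 8-day compositing
    calendar, fills gaps by linear interpolation, trains 1-3 layer
    convolutional LSTM networks on VHI image sequences, produces multi-step
    forecasts by iterative and separate (direct) strategies, and evaluates
    them with RMSE, MAE, MAPE, per-pixel error maps and persistence and
    climatology baselines. A synthetic-data generator emulating seasonal,
    spatially correlated, anticorrelated NDVI/LST fields makes the whole
    pipeline exercisable without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
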