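Package: rddair
Title: Causal Appraisal of Air Quality Interventions with Donut Regression
    Discontinuity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the causal effect of an intervention with a known start
    date (such as a mobility lockdown) on monitored air pollutant
    concentrations. Hourly concentrations are first normalized for weather and
    seasonality with a gradient-boosted tree model and covariate resampling;
    structural changes in the normalized daily series are located with an
    exact penalized change-point segmentation; sites whose change points fall
    inside a margin period around the intervention start are appraised with a
    donut sharp regression discontinuity in time, with total (lag-propagated)
    effects and Monte Carlo interval estimates. Site-level effects are turned
    into counterfactual series and annual exposure impacts, interpolated to a
    grid and areal units by residual kriging, and the spatial heterogeneity of
    areal impacts is attributed to spatial features with gradient-boosted
    trees and Shapley additive explanations. A synthetic-data generator with
    known ground truth supports end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    sandwich,
    xgboost,
    data.table,
    jsonlite,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
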