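Package: staforecast
Title: Spatiotemporally Constrained Attention Forecasting of State-Level
    Obesity Prevalence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forecasts next-year obesity prevalence from state-level
    surveillance panels (CDC DNPAO "Data, Trends, and Maps" export layout)
    with a dual-branch attention model: a temporal branch that jointly embeds
    engineered health features with sinusoidal time encodings, and a branch
    whose attention logits are modulated by an exponential temporal decay
    kernel and a correlation-derived, optionally learnable, feature
    association matrix. Includes a seeded synthetic panel generator,
    the full preprocessing chain (mean/mode imputation, IQR outlier
    replacement, z-score standardization), lag/difference/rolling-mean
    feature engineering, dual-branch consistency training with Adam,
    five forecast metrics (MAE, RMSE, sMAPE, R-squared, MASE) with paired
    significance tests, ablation arms, and permutation-sampling Shapley
    attributions with an exact enumeration mode.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    datasets,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
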