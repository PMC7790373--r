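Package: lagcv
Title: Cross-Validation Strategies and Permutation Ratios for
    Distributed-Lag Environmental Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for choosing neural-network hyperparameters on daily
    environmental health time series without breaking their serial
    structure.  Implements three cross-validation schemes for the training
    region of a chronological split (random five-fold, leave-one-block-out,
    and temporal-block forward chaining), a permutation-ratio statistic
    that measures how much of the predictive accuracy a fitted model
    contributes beyond the outcome's marginal distribution, a seeded
    feed-forward network trainer for scoring hyperparameter grids, and a
    synthetic-data generator that simulates Poisson daily death counts from
    a distributed-lag nonlinear model (spline cross-basis in temperature
    and lag, fixed pollutant effects, seasonal spline).  Packaged reference
    grids from a published Taipei 2012-2016 temperature-mortality analysis
    support exact reproduction of that study's summary arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
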