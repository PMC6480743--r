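Package: iivdsem
Title: Two-Level Dynamic Structural Equation Models for Intraindividual
    Reaction-Time Variability in Go/NoGo Tasks
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates trial-level reaction-time and error data from
    classical and prospective-memory Go/NoGo (sustained attention to
    response) tasks, preprocesses the resulting time series (outlier
    trimming, log transformation, intraindividual standard deviations),
    screens each series for stationarity with augmented Dickey-Fuller
    tests, and fits two-level first-order autoregressive dynamic
    structural equation models by Gibbs sampling with missing-data
    augmentation. Person-level means, lag-1 autoregression, and
    fluctuation amplitude are random effects that may predict
    commission-error and prospective-omission counts; posterior
    summaries include credible intervals, standardized estimates,
    between-level R-squared, and potential scale reduction diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
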