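Package: idmAUC
Title: Time-Specific AUC for Illness-Death Models with Interval-Censored
    Disease Status
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrimination performance of a binary time-dependent disease
    marker on survival when disease onset is interval-censored by a visit
    schedule. Implements the progressive three-state (illness-death) Markov
    model with Weibull or piecewise-constant transition intensities, the
    exact true incident/dynamic and cumulative/dynamic time-specific AUC of
    the marker under a Weibull generating model, plug-in AUC estimators for
    any fitted illness-death model, three estimation routes (Cox model with
    time-dependent covariate via counting processes and Aalen-Johansen
    transition probabilities, piecewise-constant panel likelihood, Weibull
    likelihood for interval-censored illness and exact death times), a
    simulator for visit-grid interval-censored datasets, and a simulation
    harness reporting bias, empirical SE and RMSE of the AUC estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    pracma
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    optparse
Config/testthat/edition: 3
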