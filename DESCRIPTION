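Package: eegdynamics
Title: Attractor Dynamics of Event-Related EEG Fluctuations Across Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates linear attractor dynamics around event-related
    potentials from epoched EEG. Single-trial activity is reduced to a
    two-component principal-component space fit on grand-average ERPs,
    z-scored within subject, and residualized against condition means;
    a 2x2 first-order autoregressive model fit in 100 ms moving windows
    yields time-resolved eigenvalue (decay-rate) estimates. Age, sex and
    behavior effects on the eigenvalue time courses are tested with
    random-intercept linear mixed models, one-dimensional threshold-free
    cluster enhancement, and a bootstrap family-wise null. Includes a
    longitudinal synthetic-cohort generator with known ground-truth
    dynamics and a latency-jitter control analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    lme4,
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lmerTest,
    withr,
    broom
Config/testthat/edition: 3
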