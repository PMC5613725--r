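Package: hrvrqa
Title: Recurrence Quantification Analysis of RR-Interval Tachograms
Version: 0.1.0
Authors@R: person("NUTECC", "Analysis Group", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Nonlinear analysis of heart-rate-variability tachograms by
    recurrence quantification analysis (RQA). Provides time-delay embedding,
    thresholded recurrence matrices and recurrence-plot rendering, the seven
    classical RQA measures (recurrence rate, determinism, mean and maximal
    diagonal line length, diagonal-line entropy, laminarity, trapping time),
    sample entropy, RR-series ingestion with two-stage artifact filtering,
    benchmark generators for random, chaotic (logistic map), periodic and
    linear (prime) model series, a synthetic heart-transplant cohort
    simulator with follow-up-dependent complexity, and the extreme-quartile
    follow-up comparison used to relate RQA variables to months after
    transplantation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
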