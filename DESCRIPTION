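Package: polarwatch
Title: Disorientation Surveillance for Opinion-Polarity Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to detect short- and long-term collective "disorientation"
    in daily opinion-polarity time series derived from labelled social-media
    posts, with vaccine-hesitancy surveillance as the motivating application.
    Provides ingestion of labelled post streams into daily
    favourable/contrary/undecided counts; day-level exact and Monte-Carlo
    multinomial goodness-of-fit tests against a yearly or running-window
    null; a chi-square running-variance test; rejection-day summaries
    against the expected false-positive count; discrete beta-kernel
    smoothing of polarity proportions (boundary-bias free) with
    leave-one-out cross-validated bandwidth; stepwise polynomial trend
    fitting; inter-annotator agreement statistics (raw pairwise accuracy
    with an exact binomial interval, and Fleiss' kappa); and a fully seeded
    synthetic opinion-stream generator with volume spikes, short
    perturbation events and a long-term trend for calibration and power
    studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
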