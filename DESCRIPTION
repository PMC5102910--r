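Package: catrace
Title: Autonomous Characterization of Calcium-Imaging Transients and Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decomposes noisy single-cell fluorescence time series (e.g. fura-2
    ratio recordings) into baseline drift, a single transient response, and
    multi-peaked (oscillatory) activity, and reports twelve kinetic and
    magnitude parameters per recording. Derivative estimation uses iterative
    total-variation regularization with data-driven parameters and noise-spike
    rejection; drift is modelled as saturating-exponential plus linear trends
    in up to two epochs; the transient is fitted as a Hill-type activation and
    deactivation joined by a C1 cubic Hermite spline; oscillatory peaks are
    detected from model residuals and split into stochastic and coherent
    subsets by Gaussian-mixture clustering with a gap-statistic model choice.
    Includes a synthetic-recording generator with known ground truth and
    Bland-Altman/correlation agreement statistics for method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    stats,
    utils,
    minpack.lm,
    pracma,
    mclust,
    readxl,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
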