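Package: gmmwake
Title: Nanopower Analog Gaussian Mixture Wake-Up Classifier for EEG Seizure Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Software model of an always-on analog wake-up classifier for
    epileptic seizure prediction from single-channel EEG. Implements the ideal
    diagonal-covariance Gaussian mixture model (GMM) classifier with
    expectation-maximization training; a behavioral (equation-level) model of
    its subthreshold analog realization built from cascaded bump circuits and
    a winner-take-all stage, including GMM-to-circuit parameter mapping and
    device-mismatch Monte-Carlo analysis; EEG windowing and band-power feature
    extraction (peak-to-peak voltage, alpha and split gamma energy fractions);
    ictal-state labeling with alarm-based sensitivity and window-based
    specificity; a duty-cycled system power model; and synthetic feature and
    EEG generators so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
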