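Package: dendsum
Title: Quantification of Nonlinear Dendritic Integration from Glutamate
    Uncaging Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying supralinear (and sublinear) dendritic
    integration from two-photon glutamate uncaging experiments in which
    somatic voltage responses to near-synchronous stimulation of an
    increasing number of dendritic locations are compared against the
    arithmetic sum of asynchronously evoked unitary responses.  Implements
    the percent-nonlinearity index for peak amplitude and 100-ms voltage
    integral, delta-F/A quantification of two-channel calcium linescans
    with a linearly interpolated expectation, trace preprocessing
    (Savitzky-Golay filtering, action-potential exclusion, uncaging-artifact
    removal, cycle averaging), estimation statistics (bias-corrected and
    accelerated bootstrap confidence intervals and permutation t-tests),
    and a synthetic experiment generator with known ground truth for
    end-to-end validation.
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
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
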