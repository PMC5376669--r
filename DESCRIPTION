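Package: intertrial
Title: Trial-History Behavior and Neural Population Analysis for
    Interval Categorization Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a two-alternative interval
    categorization task in which the stimulus sequence is coupled to the
    subject's outcomes (the stimulus repeats after an error and is drawn
    uniformly after a correct response). Provides a generative task and
    agent simulator, psychometric-curve fitting with lapse rates and
    bootstrap comparisons, win-stay/lose-switch statistics, a log-link
    spike-count encoding model with permutation significance and exact
    binomial population tests, z-scored linear weight-correlation
    analyses, ROC/AUC and PSTH single-neuron characterization, and
    balanced subsampled cross-validated population decoding with
    label-shuffle null tests, conditioned decoding, and information
    ranking. A synthetic-neuron layer generates spike counts and spike
    times from the same encoding model, so every analysis stage is
    verifiable by parameter recovery and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
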