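Package: semgrip
Title: Grip-Force Monitoring from Wireless Surface Electromyography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end toolkit for estimating isometric grip force from
    two-channel surface electromyography (sEMG) recorded by a wireless,
    packet-based acquisition system.  Provides a bit-exact codec for the
    116-byte transfer protocol of the acquisition terminals and per-channel
    stream reconstruction; zero-phase Butterworth band-pass preprocessing with
    full-wave rectification and maximum-voluntary-contraction (MVC)
    normalization; sliding-window extraction of six time- and frequency-domain
    features (iEMG, RMS, waveform length, Shannon entropy, median frequency,
    mean power frequency); a bald eagle search (BES) metaheuristic for bounded
    continuous optimization, used to tune Random Forest regression
    hyperparameters; agreement statistics (cross-correlation coefficient and
    relative agreement) for validating an acquisition system against a
    reference device; and a synthetic-session generator that emulates the
    acquisition chain so every stage is testable without access to recorded
    subject data.
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
    jsonlite,
    yaml,
    readr,
    withr,
    zoo,
    signal,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
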