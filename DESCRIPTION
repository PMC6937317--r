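Package: lfpbeta
Title: Learning-Related Beta Oscillations in Multi-Site LFP Recordings
Version: 0.1.0
Authors@R:
    person("LFP", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for beta-band (17-28 Hz) oscillations in
    multichannel local field potential recordings from a two-alternative
    choice odor discrimination task: Morlet wavelet time-frequency
    decomposition, MAD-threshold artifact rejection, per-trial log-normalized
    beta burst amplitude, debiased weighted phase lag index (WPLI^2)
    functional connectivity with surrogate max-statistic significance
    testing, behavioral learning-criterion session labeling, and bootstrap
    group summaries. Includes a task-structured synthetic LFP generator with
    ground truth so every stage has a parameter-recovery test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
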