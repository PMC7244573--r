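Package: blinktrace
Title: Bayesian State-Trace Analysis and Serial-Experience Modelling of the
    Attentional Blink
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether report accuracy and subjective visibility
    in attentional-blink experiments can be driven by a single latent process.
    Implements order-constrained Bayesian state-trace analysis under an
    encompassing prior (monotonic versus non-monotonic Bayes factors,
    constraint-validity Bayes factors, empirical reduction of literature
    constraint sets, grouped Bayes factors across participants), a
    minimal-visibility ("sight-blind recall") accuracy analysis, a synthetic
    RSVP trial generator with controllable monotone or non-monotone latent
    structure, and an STST-lite simulator with a serial-experience readout
    that produces per-lag behaviour and virtual P3 traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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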