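Package: ildsense
Title: Psychometric Analysis of Interaural Level Difference Sensitivity
    Under Bilateral Cochlear-Implant Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-alternative forced-choice (2AFC) lateralization
    experiments with bilateral cochlear implants: synthesis of charge-balanced
    biphasic pulse-train stimuli with interaural level differences (ILD) in dB
    of pulse amplitude, clinical current-level unit conversions, seeded
    simulation of trial-level behavioral data from ground-truth psychometric
    parameters, maximum-likelihood fitting of probit-with-lapse, bounded-linear
    and null response models with deviance-based model selection, just
    noticeable difference (JND) and slope sensitivity metrics with Wilson score
    intervals, regression of sensitivity against log pulse rate, and a
    reproducible end-to-end pipeline with manifested artifacts.
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
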