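Package: avspike
Title: ROC Selectivity, Multisensory Integration and Population Decoding
    for Trial-Aligned Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spike trains recorded while animals perform
    a two-alternative forced-choice audiovisual discrimination task. Provides
    trial-aligned session input/output, a Poisson synthetic-session generator
    emulating cue-tuned neurons with pairing-specific multisensory interaction,
    peristimulus time histograms with Gaussian smoothing and baseline
    z-normalisation, ROC-based cue-selectivity and multisensory-interaction
    indices with permutation nulls, a bootstrap additive-model test with
    scaling-coefficient estimation, time-resolved pseudo-population decoding
    with linear support vector machines and shuffled-label nulls, and
    population-level summaries and group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
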