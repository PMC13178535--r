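Package: cascadeTFA
Title: Cascade Transfer Function Analysis of Dynamic Cerebral Autoregulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transfer function analysis of the arterial pressure to cortical
    oxygenation pathway, decomposed into serial macrovascular (pressure to
    cerebral blood flow velocity) and microvascular (flow velocity to
    oxyhaemoglobin) stages. Implements beat-to-beat preprocessing of
    multichannel haemodynamic recordings, Welch cross-spectral estimation of
    gain, phase and magnitude-squared coherence, the two-component cascade
    combination (product of gains, sum of phases, product of coherences) with
    band summaries and low-frequency phase-wrapping exclusion, Monte Carlo
    critical coherence thresholds, cohort-level validation of the cascade
    against the directly estimated total pathway, and a synthetic
    cerebrovascular signal simulator with known ground-truth stage dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    zoo,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
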