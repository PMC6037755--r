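Package: attnvar
Title: Attentional Fluctuations and Shared Variability in Visual Cortical Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cued change-detection experiments probing how
    fluctuations in attentional state drive correlated variability in primary
    visual cortex. Generates the dynamic orientation-noise stimulus and session
    schedules of the paradigm, simulates orientation-tuned spiking populations
    under a latent switching attention state, and implements the full analysis
    chain: threshold-based spike detection, stimulus-conditioned tuning
    estimation with permutation tests, von Mises fits with condition-specific
    gain and offset, block-wise spike-count correlations and Fano factors,
    shift-corrected cross-correlograms and the cumulative correlation
    coefficient r_CCG, psychometric fitting, microsaccade detection, current
    source density laminar assignment, and session-level repeated-measures
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    data.table,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
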