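Package: capnet
Title: Transient EEG Co-Activation Patterns and Resting-State Network
    Correspondence
Version: 0.1.0
Authors@R:
    person("Capnet", "Developers", email = "capnet@example.org",
           role = c("aut", "cre"))
Description: Tools for extracting recurring transient co-activation patterns
    (CAPs) from band-limited EEG source envelopes with correlation-distance
    k-means, estimating time-averaged resting-state networks (RSNs) with
    time-frequency independent component analysis and envelope regression,
    and quantifying their spatial and temporal correspondence, hemispheric
    symmetry, inter-participant consistency, and reproducibility across
    clustering parameters. Includes minimum-norm source imaging with
    per-timeframe generalized cross-validation regularization, and a fully
    seeded synthetic-cohort generator with planted ground truth so the whole
    pipeline is testable without access to raw EEG recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    clue,
    lme4,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
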