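Package: burstnet
Title: Network Bursts, Burst Predictors, and Avalanche Criticality on
    Multielectrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spontaneous multi-unit activity (MUA)
    recorded on multielectrode arrays. Detects MUA from high-pass filtered
    voltage traces, finds network bursts against a rate-preserving
    permutation null, scores per-channel burst predictors, extracts
    neuronal avalanches and fits bounded discrete power laws by maximum
    likelihood (Hurwitz-zeta normalizer), estimates the critical branching
    parameter from ancestor/descendant counts, and compares matched
    pre/post-insult sessions. A probabilistic branching network model
    generates synthetic rasters so every stage can be exercised and
    calibrated without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
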