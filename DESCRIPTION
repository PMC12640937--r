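Package: patchpharm
Title: Cardiac Ion Channel Pharmacology from Patch-Clamp and Action-Potential
    Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for cardiac safety pharmacology: voltage-clamp
    sweep models and plain-text I/O for hERG, L-type calcium (I_CaL) and late
    sodium (I_NaL) recording protocols; isolation of the drug-sensitive
    current by reference-blocker or passive (ohmic leak) subtraction;
    per-cell fractional inhibition with an automated amplitude-stability
    gate; constrained variable-slope Hill fits with bootstrap or Wald 95
    percent confidence intervals, predicted inhibition at clinical exposure
    and channel-selectivity ratios; extraction of action-potential
    repolarization statistics (APD30/50/90, triangulation, short-term
    variability) from paced microelectrode trains with quality-control and
    change-threshold rules; and a synthetic-data generator with known ground
    truth (rundown, wash-in, leak, jitter) so every stage is verifiable end
    to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
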