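Package: gistmem
Title: Time-Dependent Memory Transformation: Behavior, FIR, RSA and gPPI Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for time-dependent transformation of detailed
    into gist-like recognition memory. Scores recognition behavior (hit and
    false-alarm rates by lure type and emotion, a confidence-weighted memory
    score, and the detailed/transformed/forgotten categorization of old-lure
    pairs), builds fMRI design matrices (canonical double-gamma HRF and
    7-bin finite impulse response bases with discrete-cosine drift), fits
    ROI-level GLMs with optional AR(1) prewhitening, extracts group-defined
    peak responses from FIR time courses, estimates single-trial t-patterns,
    constructs generalized psychophysiological interaction (gPPI) models,
    computes trial-wise representational dissimilarity matrices (1 - Pearson
    r) with categorical model-RDM fits and cross-group comparisons, and
    provides the inferential machinery (mixed ANOVA with generalized eta
    squared and Greenhouse-Geisser correction, Welch and paired t-tests,
    Pearson-Filon comparison of overlapping dependent correlations). A
    synthetic-data module simulates cohorts with the assumed statistical
    structure so the full pipeline is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
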