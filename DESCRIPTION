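Package: fcmotion
Title: Motion-Aware Resting-State Functional Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying head micro-movement in resting-state
    fMRI (framewise displacement, DVARS, run-level RMS), for applying ten
    motion-correction procedures (motion-parameter regression, partial
    correlation with motion covariates, group-level mean-FD adjustment,
    motion matching, volume censoring with mask augmentation, and a
    distance-polynomial r-value correction), and for the downstream
    analyses these procedures feed: edge-wise age association with
    short/long-range distance contrasts, a frame-removal degradation
    simulation, support-vector-regression brain-maturity prediction with
    Von Bertalanffy growth-curve normalization, leave-one-out
    cross-validated SVM classification of ADHD subtypes, and node-strength
    summaries of consensus features. A synthetic cohort generator with
    planted age, subtype, and distance-dependent motion-artifact structure
    supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    signal,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
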