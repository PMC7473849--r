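Package: bolddecode
Title: Searchlight and Temporal Decoding of Choice- and Action-Predictive
    BOLD Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and multivoxel pattern analysis of slow event-related
    fMRI experiments in which a binary memory choice (old/new) is mapped onto
    a motor effector (eye/hand), with the choice-response association reversed
    between two subject groups. Provides counterbalanced trial-schedule
    generation, synthetic BOLD data with planted, locally distributed
    condition-dependent patterns, condition and single-trial (beta-series)
    GLM estimation with execution-phase residualization, between-subject
    (leave-one-subject-out) and within-subject searchlight decoding with a
    linear support vector machine, FDR and cluster-extent thresholding of
    accuracy maps, regional evidence-modulation tests with a linear mixed
    model, frame-wise temporal decoding and temporal generalization matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    igraph,
    jsonlite,
    lme4,
    lmerTest,
    RNifti,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
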