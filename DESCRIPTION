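Package: sustainr
Title: Subtype and Stage Inference for Amyloid and Tau Progression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Event-based modelling of Alzheimer's-related amyloid-beta and
    tau pathology progression from cross-sectional biomarker data. Implements
    z-score and ordinal (severity-score) subtype-and-stage inference with
    greedy ascent plus MCMC over event orderings, cross-validated model
    selection (CVIC), kernel-density mixture scoring of continuous
    neuropathology measures against global CERAD/Braak ratings,
    control-cohort covariate adjustment, early-stage group stratification by
    APOE e4 carriage, and longitudinal subtype-consistency and trajectory
    analyses. Includes a synthetic cohort generator with ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
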