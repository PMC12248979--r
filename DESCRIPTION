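Package: fixfill
Title: Microsaccade Detection and Mixed-Model Analysis of Perceptual
    Filling-In Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing fixational eye movements in perceptual
    filling-in (Troxler-type fading) experiments. Implements binocular
    microsaccade detection with an elliptic velocity-threshold criterion,
    ocular drift (retinal slip) quantification on a fine spatial grid,
    trial-level perceptual metrics (filling-in time, immobilization time,
    exclusion bookkeeping), causal-kernel microsaccade rate dynamics
    aligned to the perceptual report, and linear mixed-effect inference
    with participant-level case bootstrap and Bonferroni-corrected
    percentile confidence intervals. A synthetic-data generator produces
    complete experiments (binocular gaze traces with known injected events
    and trial outcomes drawn from a known generative structure) so every
    stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
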