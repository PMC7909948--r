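Package: pupilstate
Title: Dissociating Task Engagement and Pupil-Indexed Arousal Effects on Sensory Neural Firing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: State-dependent encoding models for single-unit firing rates
    recorded during alternating passive and active behavior blocks. Firing is
    modeled as a baseline (DC) and gain re-weighting of the stimulus-evoked
    PSTH by two state regressors, binary task engagement and continuous
    pupil-indexed arousal, each passed through a saturating sigmoid
    nonlinearity. Cross-validated shuffle controls partition explained
    variance into task-unique and pupil-unique components; modulation indices
    between behavioral conditions are decomposed the same way. Includes
    signal-detection behavioral metrics (hit rate, false-alarm rate, d-prime),
    hierarchical bootstrap and permutation inference, reverse-correlation
    spectro-temporal receptive field estimation, and a synthetic-session
    generator with stored ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
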