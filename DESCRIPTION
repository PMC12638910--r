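Package: eegstages
Title: Multi-Task, Multi-Stage Learning EEG Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-controlled segmentation, relative band-power features,
    phase-lag-index and information-transfer connectivity, group task-related
    component analysis, non-parametric stage and task comparisons, and
    MRMR-ranked machine-learning discrimination of learning stages for
    14-channel consumer-grade EEG recorded during multi-session learning
    tasks. Includes a synthetic EEG generator with controllable
    stage-dependent oscillatory structure, channel-pair phase coupling and
    injectable artifacts, so the whole pipeline is exercisable end-to-end
    without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    e1071,
    igraph,
    jsonlite,
    nnet,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
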