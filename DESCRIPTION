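Package: entrainr
Title: Multi-Timescale Analysis of Collective Attention Entrainment to
    Broadcast Conversation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for time-locking a timestamped social-media message
    stream to an annotated conversational event (speech turns,
    interruptions, salient remarks) and modelling collective attention at
    three timescales: linear mixed-effects models of per-second mention
    rate against speaker, speaking time and interruptions; a decay-times-
    sigmoid kernel for the burst and self-sustained adoption of salient
    remarks ("memes"), fitted by correlation-maximising parameter search;
    and a quadratic long-term trend of overall attention.  The timescales
    are combined in a single multiscale regression with unique-variance
    decomposition and cross-event transfer prediction.  Includes a
    Poisson point-process generator of synthetic debates and entrained
    message streams with known ground truth, so every pipeline stage is
    testable without access to raw platform data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    knitr
Config/testthat/edition: 3
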