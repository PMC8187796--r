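Package: prosmile
Title: Smile-Based Prediction of Prosocial Behavior in Robot-Assisted Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the link between smiling and prosocial
    behavior in child-robot interaction sessions. Implements a facial
    surface-EMG smile-detection chain (zero-phase band-pass filtering,
    fixed-point independent component analysis, RMS envelope features and a
    per-participant feed-forward neural-network classifier), fusion of
    EMG-estimated smiles with video annotation timelines, extraction of
    timed analysis windows and per-second pre-behavior coding, joint and
    conditional probability tables over binary behavior flags with
    subject-wise leave-one-out cross-validation, two-coder intraclass
    correlation, and a seeded synthetic-data generator emulating both the
    EMG signal structure and the behavioral event chain so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    nnet,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
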