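Package: fluorotrack
Title: Dynamic Target Tracking for Videofluoroscopic Swallowing Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking moving targets in low-contrast grayscale
    fluoroscopy video, built around the videofluoroscopic swallowing study
    (VFSS) setting. Provides discrete-point tracking of an amorphous,
    deforming barium bolus; an improved inter-frame difference detector
    with residual-image cancellation; a combined kernelized position
    (KCF-style) plus scale-space (DSST-style) correlation-filter tracker
    for rigid tissue and organ targets with watershed edge correction;
    ViBe and EGMM background-subtraction baselines and a MOSSE baseline
    tracker; a detection-free online multi-target manager reporting
    inter-target geometry in a spine-anchored coordinate frame;
    evaluation metrics (average pixel error, average overlap ratio,
    success rate); and a seeded synthetic fluoroscopy-sequence generator
    with ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
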