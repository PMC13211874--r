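Package: flymotion
Title: Analysis Pipeline for Fly Motion-Vision Imaging, Behavior, and Connectomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyze two-photon calcium imaging of fly visual
    neurons and spherical-treadmill behavior: automated extraction of
    direction-selective axon terminals (Otsu foreground detection,
    responsiveness filtering, per-pixel DSI/CSI, area-constrained
    average-linkage clustering), reverse-correlation estimation of
    spatiotemporal receptive fields from ternary white-noise stimuli with
    prediction-R2 validation and Gaussian FWHM extraction, flash and
    moving-bar response metrics including the circular L_dir tuning vector,
    optomotor percent-recovery quantification for paired-edge stimuli, and
    synapse-table summarization with proofreading and count filters. A
    synthetic-data generator simulates linear-nonlinear model neurons,
    imaging movies with planted terminals, turning traces, and synapse
    tables with known ground truth so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    jsonlite
Encoding: UTF-8
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
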