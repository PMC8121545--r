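Package: pmlearn
Title: Bayesian Learning with Performance Monitoring and Trial-Level
    Feedback Analysis
Version: 0.1.0
Authors@R:
    person("pmlearn", "maintainers", email = "pmlearn@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for studying how response-based
    performance monitoring (outcome predictions and confidence) regulates
    learning from feedback in a time-estimation task.  Implements a Bayesian
    observer that infers an unknown target interval and feedback scale by
    grid approximation, fusing its intended response with a noisy efference
    copy by precision weighting, together with two reduced variants
    (average-confidence and feedback-only).  Includes simulation harnesses
    for model comparison, confidence-calibration sweeps and Shannon-surprise
    grids; a trial-level behavioral pipeline (outlier filtering, reward and
    sensory prediction errors, confidence-calibration index, predictor
    scaling, fixed-effects regression); single-trial ERP feature extraction
    (FRN peak-to-peak, P3a/P3b region-of-interest window means, artifact
    rejection); and generators for synthetic behavioral tables and EEG
    epochs so the full pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
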