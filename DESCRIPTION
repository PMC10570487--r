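Package: dyadsync
Title: Interbrain Phase-Locking Analysis for Shared-Gaze Hyperscanning Dyads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dual-EEG ("hyperscanning") recordings of dyads
    performing remote joint-attention tasks with shared gaze. Provides a
    synthetic dyad generator with known interbrain phase coupling and gaze
    coordination, deterministic EEG conditioning (zero-phase FIR band-pass
    filtering, downsampling, mean-mastoid re-referencing, stimulus-locked
    epoching), band-wise analytic-signal extraction and cross-brain
    connectivity (phase locking value, corrected imaginary PLV, weighted
    phase lag index), a shuffled-dyad bootstrap null model with
    false-discovery-rate control, dyadic eye-tracking metrics (target-search
    times, inter-gaze distance, gaze heatmaps with Pearson/SSIM/Jaccard
    similarity), repeated-measures and mixed factorial ANOVAs, and an
    end-to-end reproducible pipeline over XDF or simulated input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    tools,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    optparse
VignetteBuilder: knitr
Config/testthat/edition: 3
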