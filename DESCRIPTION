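Package: optofear
Title: Optogenetic Spike-Train Response Detection and Fear-Renewal
    Behavioral Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for optogenetic terminal-stimulation
    experiments in prefrontal cortex and for context-dependent fear-renewal
    behavior.  Detects light-evoked responses in sorted spike trains with a
    jitter-surrogate test on one-millisecond peri-event histogram bins,
    calibrates the detector's chance level by shuffling the order of
    inter-spike intervals, types responses as short-latency excitation or
    pulse-locked inhibition with offset rebound, and summarizes population
    responsiveness.  A companion behavioral arm aggregates percent-freezing
    tables over learning stages, applies an extinction criterion, runs
    planned unpaired t-tests at stimulation timepoints, and pools control
    groups when they are statistically indistinguishable.  A synthetic-data
    module generates 20 Hz pulse-train protocols, gamma-renewal background
    spiking with injected ground-truth responses, and freezing tables, so
    the full pipeline runs and is tested without any recorded data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
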