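Package: dexstates
Title: Cortical LFP Dynamics and Behavioral Endpoints During
    Alpha-2-Adrenergic Agonist Anesthesia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-channel intracortical local field
    potential (LFP) recordings during dexmedetomidine-induced unconsciousness
    and recovery. Provides behavioral endpoint detection (loss of
    consciousness, return of consciousness, return of pre-anesthetic
    performance) from trial logs, multitaper spectrograms and channel-pair
    coherence, z-score based sleep-spindle event detection and
    characterization with Hilbert-Huang peak-frequency estimation, a
    three-dimensional spectral-power-ratio state space built from per-ratio
    first principal components with trajectory density and speed metrics,
    and frequency-wise repeated-measures statistics. A seeded synthetic
    session generator with ground-truth state timelines makes every stage
    testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    nortest,
    signal,
    stats,
    tools,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
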