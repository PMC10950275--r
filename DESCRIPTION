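Package: plantephys
Title: Stimulus-Locked Analysis of Plant Electrophysiology Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing extracellular plant electrophysiology
    recordings stored as PCM WAV files with keyboard event markers:
    artifact rejection (fast movement spikes, amplifier clipping, elevated
    baselines), stimulus-locked wound-potential and action-potential
    detection against the pre-stimulus signal range, normalized
    peak-aligned species response libraries, and conduction-velocity
    estimation from two-channel peak lag. Includes a seeded synthetic
    recording generator modelling AC-coupled amplifier filtering, drift,
    mains hum, movement and clipping artifacts, and slow propagating
    responses, so the full pipeline is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
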