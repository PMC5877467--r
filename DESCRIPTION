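Package: smokesense
Title: Multi-Sensor Wearable Pipeline for Cigarette Smoking Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for a multi-device wearable
    suite that monitors cigarette smoking behavior: an instrumented lighter
    (press/release events), a hand module (6-axis IMU, pedometer, RF
    proximity transmitter) and a chest module (respiratory inductance
    plethysmography read out as LC-oscillator pulse counts, bioimpedance
    respiration, Lead-I ECG, chest accelerometer, RF proximity receiver,
    GPS). Provides forward models that render a ground-truth behavior
    timeline through every sensor with realistic noise and per-device clock
    drift, linear clock-drift compensation, per-sensor zero-phase denoising
    chains, peak- and threshold-based event detectors (breaths, R-peaks,
    hand-to-mouth proximity, cigarette consolidation from lighter logs),
    usability screening, and study-level summaries including sensor
    agreement, great-circle GPS displacement and the LC resonance physics
    of the respiration belt.
License: MIT
Encoding: UTF-8
Imports:
    geosphere,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
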