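Package: adlmotion
Title: Bilateral Upper-Limb EMG and IMU Analysis of Drinking and Eating
    Activities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processing pipeline for wearable recordings of the upper limb
    during activities of daily living (drinking from a cup, eating with a
    spoon). Converts 12-bit surface electromyography counts to millivolt
    activation envelopes (rectification and moving-average smoothing) and
    inertial-measurement-unit orientation quaternions to anatomically signed
    shoulder joint angles (intrinsic Z-Y-X Euler decomposition, unwrapping,
    smoothing), segments both by a seven-phase video-annotated task model,
    time-normalizes each movement cycle to a common 0-100 percent axis,
    averages within and across subjects, and summarizes per-muscle activation
    peaks and per-motion joint-excursion peaks. Includes a deterministic
    synthetic-recording generator with ground-truth sidecars for
    parameter-recovery validation, device-dialect CSV/JSON readers and
    writers, and report tables in the field's standard layout.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
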