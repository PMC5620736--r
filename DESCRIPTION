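Package: bmsense
Title: Behaviour Monitoring from Passive Infrared Motion Sensor Streams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Learns a per-weekday, per-hour probabilistic model of a single
    resident's room-to-room mobility from passive infrared (PIR) motion
    sensor event logs, and monitors the stream in quasi-real time for
    deviations from the learned routine. The model holds, for every weekday
    and time-of-day interval, a room transition matrix together with global,
    inter-room and intra-room activity rates and longest continuous stays.
    Detection combines a normalised location-likelihood estimator, a
    three-state confirmation automaton with hysteresis timers, and a
    rule-based classifier mapping confirmed deviations to OverSleeping,
    LessSleeping, NotBackHome or Dead. Includes a synthetic single-resident
    mobility simulator with anomaly injection, a reader for CASAS-format
    smart-home logs, and evaluation metrics (detection delay, confirmation
    time, weekly false-positive rate, per-class accuracy).
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
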