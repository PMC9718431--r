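Package: adreflex
Title: Non-Invasive Detection of Autonomic Dysreflexia from Sympathovagal Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for detecting autonomic dysreflexia
    (AD) in a rodent spinal-cord-injury model from non-invasive sensors. Generates
    seeded multi-channel physiological recordings (10 kHz ECG and skin sympathetic
    nerve activity, tail-cuff blood pressure, skin temperature) with annotated
    stimulus epochs; conditions the signals into beat series and integrated skNA
    burst events; extracts five sympathovagal features (burst count, average iskNA,
    medianNN, RMSSD, pnn5) on 15-second windows with per-trial-day min-max scaling;
    labels AD events from blood-pressure criteria; and trains and evaluates a
    feed-forward neural classifier that separates AD from other sympathetic
    stressors, together with the accompanying statistical battery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    pROC,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
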