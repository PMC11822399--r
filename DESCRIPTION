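Package: digiphen
Title: Digital Phenotyping Pipeline for Wearable and Smartphone Sensor Streams
Version: 0.1.0
Authors@R:
    person("HOPE-S", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates and analyses passive-sensing data from wrist wearables
    and smartphones in a psychosis outpatient cohort. Generates synthetic raw
    sensor streams (staged sleep, heart rate, steps, GPS mobility, touchscreen
    taps, messaging, power-state logs) coupled to baseline clinical scales,
    extracts twelve daily digital measures, aggregates them into visit-level
    digital markers under windowing and validity rules, computes hourly-window
    data-completeness rates, and runs a standardized no-intercept regression
    screen of every digital marker against every clinical measure, rendered as
    a coefficient heat map.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pheatmap,
    withr
Config/testthat/edition: 3
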