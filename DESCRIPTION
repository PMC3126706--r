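Package: lysisflow
Title: Virtual Pulsatile-Flow Rig for Time-Continuous In-Vitro Thrombolysis
    Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A digital twin of an in-vitro pulsatile-flow thrombolysis rig:
    a lumped-parameter hydraulic circuit with a custom clot carrier, virtual
    transit-time ultrasonic flow metering and dual pressure sensing with
    realistic noise and drift, a phenomenological clot-lysis model
    (mechanical attrition, compaction, rt-PA and ultrasound-enhanced
    enzymatic lysis), and the full analysis chain that converts drift-
    corrected pressure declines across the carrier into normalized lysis
    readouts and, via fitted calibration surfaces and monotone rating
    curves, into filling and lysis trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    minpack.lm,
    data.table,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
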