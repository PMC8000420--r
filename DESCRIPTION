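Package: kneeflow
Title: In Vitro Draining-Knee Reactor Model of Local Antibiotic Delivery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates antibiotic concentration profiles in a constant-volume,
    well-mixed flow reactor that mimics post-operative drainage of a revised
    knee joint. A clinically derived power-law drainage trendline is
    discretized into a stepwise pump schedule that flushes a 75 mL compartment
    fed by antibiotic depots (antibiotic-loaded PMMA spacer, absorbable
    calcium sulfate beads, or a powdered vancomycin bolus). Includes a
    synthetic effluent-measurement generator with detection-limit censoring,
    and the downstream exposure analysis: geometric means of log10
    concentrations, between-arm log differences, trapezoidal AUC windows,
    time above a biofilm-eradication threshold, equal-variance t-tests, and a
    zone-of-inhibition potency calibration against reference organisms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
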