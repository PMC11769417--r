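Package: strikevel
Title: Strike Velocity and Test-Retest Reliability from Smartphone
    Accelerometer Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Measures punch and kick impact velocities from low-cost
    smartphone accelerometer recordings (PhyPhox CSV exports). Segments
    individual strikes from the triaxial acceleration norm by peak
    detection and backward threshold crossing, integrates acceleration to
    impact velocity with the trapezoidal rule, and computes the full
    test-retest reliability battery used in sports science: within- and
    between-day coefficients of variation, ICC(3,1) with Shrout-Fleiss
    confidence intervals, the standard error of measurement from a
    two-way repeated-measures ANOVA, Bland-Altman limits of agreement,
    and paired t-tests. Includes a synthetic inertial-signal generator
    with analytic ground truth (half-sine pulse model, cohort variance
    components) for end-to-end validation without recorded data, plus a
    sampling-rate study of detection and integration bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
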