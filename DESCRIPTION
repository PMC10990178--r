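Package: springgait
Title: Spring-Mass Running Biomechanics from Step Timing with Two-Group
    Repeated-Measures Statistics
Version: 0.1.0
Authors@R:
    person("Volo", "Runner", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives temporal gait variables (step frequency, swing time,
    duty factor) and sine-wave spring-mass variables (peak vertical ground
    reaction force, centre-of-mass displacement, leg compression, leg
    stiffness) from ground contact and flight times measured by photocell
    systems. Ingests per-step trial records, applies a speed-tolerance
    acceptance rule, and aggregates to one timing pair per participant per
    speed. Provides the companion statistical workflow for two-group cohort
    comparisons across running speeds: assumption checks, mixed
    (between x within) repeated-measures ANOVA with sphericity handling,
    Holm-adjusted post-hoc contrasts, Cohen's d, and confidence intervals
    of mean differences. A synthetic-cohort generator, calibrated by
    numerical inversion of the spring-mass model against built-in reference
    group summaries, makes the full pipeline testable without raw data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
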