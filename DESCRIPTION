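Package: cannulaskill
Title: Motion Smoothness and Outcome Metrics for Simulated Cannulation
    Skill Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes motion-smoothness process metrics (task time, path
    length, velocity-profile peaks, log dimensionless jerk, spectral arc
    length) from needle-tip kinematics recorded on a hemodialysis
    cannulation simulator, studies how the Savitzky-Golay smoothing
    window span affects them, and compares their association with three
    skill indicators (flash ratio, global rating sheet score, years of
    experience) via standardized simple regressions with Tukey-adjusted
    pairwise slope comparisons.  Includes a seeded synthetic-cohort
    generator (minimum-jerk submovement trajectories, calibrated sensor
    noise, flashback simulation, latent-skill-linked indicators) so the
    full pipeline is testable without access to restricted clinical
    sensor data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
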