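Package: cutrisk
Title: ACL Injury Risk Screening from Wearable-Sensor Cutting Biomechanics
Version: 0.1.0
Authors@R:
    person("cutrisk", "maintainers", email = "maintainers@cutrisk.example.org",
           role = c("aut", "cre"))
Description: End-to-end screening pipeline for anterior cruciate ligament (ACL)
    injury risk profiles from wearable-sensor joint kinematics of change-of-
    direction (cutting) maneuvers. Detects foot contacts from pelvis vertical
    velocity, locates the final pre-cut stance window, estimates the cut angle
    with a multistep filter chain, extracts entry/exit velocity-acceleration
    performance metrics and inter-limb sagittal asymmetry, classifies nine
    biomechanical risk factors against sex-, task-, and frame-specific
    normative thresholds, and assembles clinician-facing per-player and cohort
    reports. Includes a synthetic cut-trial generator with embedded ground
    truth so the full pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
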