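Package: quadgait
Title: Quadruped Gait Kinematics, Interlimb Coordination and Footfall Indices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for rodent overground and swimming locomotion:
    sagittal hindlimb joint-angle kinematics from four-marker trajectories,
    step-cycle segmentation with spatiotemporal measures, interlimb circular
    phase with a lead-limb-free linear transform and 2-SD irregularity
    classification against uninjured-control variability, footfall-pattern
    coordination indices (regularity index, central pattern index, plantar and
    dorsal stepping indices), speed-dependent exponential-decay curve fits with
    prediction intervals, circular descriptive statistics, the Watson
    two-sample U2 test and two-proportion z tests. Includes a fully seeded
    synthetic gait generator that emulates the statistical structure of four
    behavioral conditions (uninjured/spinal-cord-injured, with and without
    conditional silencing of long ascending propriospinal neurons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
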