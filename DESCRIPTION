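Package: bcivmr
Title: Simulation and Analysis of Visuomotor Rotation Adaptation Under
    Brain-Computer Interface Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying short-term visuomotor rotation (VMR)
    adaptation in 3D center-out brain-computer interface (BCI) tasks. The
    package pairs a closed-loop session simulator (linearly tuned units with
    a shared low-dimensional latent structure, a velocity Kalman filter
    decoder, and a trial-by-trial re-association learning rule) with the
    full analysis pipeline: trajectory alignment into a common
    target/perturbation frame, midpoint angular error and exponential
    adaptation fits, offline population re-decoding with deflection and
    relative-gain readouts, memory-period decoding with 8-way target
    classification, principal-component alignment indices, preferred
    direction shifts, decoder contribution scores, and a hierarchical model
    linking planning to movement re-aiming.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
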