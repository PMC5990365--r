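Package: eventmass
Title: Event-Based Mass Estimation and Reach Prediction Under Visuomotor Delay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Simulates a delayed virtual pong game played with a planar
    five-bar-linkage manipulandum by a parametric artificial player, estimates
    the perceived "mass modifier" of the device from visual and proprioceptive
    velocity measurements at ball-paddle collision events via
    maximum-likelihood cue combination, and predicts the resulting hypermetria
    or hypometria of blind reaching movements by replaying inverse-dynamics
    feedforward commands computed on the mass-augmented model. Includes the
    full five-bar kinematics and Euler-Lagrange dynamics, the direction-
    dependent effective endpoint mass, the event-driven game simulator, the
    estimation chain, and cohort-level experiment replications.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
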