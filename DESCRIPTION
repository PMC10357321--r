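Package: kinprime
Title: Single-Trial Kinematic Encoding and Readout of Intention with Priming Analyses
Version: 0.1.0
Authors@R: person("kinprime", "maintainers", email = "kinprime@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how movement kinematics encode an agent's
    intention and how individual perceivers read that information out, at the
    single-trial level. Implements elastic-net regularized logistic encoding and
    readout models with leave-one-video-out cross-validation, sign-adjusted
    log-odds information indices, permutation and surrogate null controls,
    zero-readout prime detection, and the downstream kinematic-priming analyses
    of response times, initial fixations, and confidence using gamma, logistic,
    and cumulative-link mixed-effects models. Includes a calibrated synthetic
    generator of reach-to-pour/reach-to-drink kinematics and simulated
    perceivers with known ground truth for parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    lme4,
    MASS,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
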