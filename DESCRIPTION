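Package: camtrigger
Title: Experimental Estimation of Camera-Trap Trigger Probability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing experimental
    detection trials that estimate the probability an animal passing
    through a camera trap's field of view triggers the sensor. Fits
    binomial-response distance-sampling detection functions (exponential,
    half-normal and hazard-rate families, optionally combined with a
    logistic mixture that allows reduced detection immediately beneath
    the camera) by maximum likelihood, ranks candidates by AIC, and
    conditions a second-stage logit-link covariate regression (body size,
    camera model, lens height, aiming distance, vertical angle, speed,
    sun position) on the selected detection function, with backwards
    stepwise selection, marginal effects and ROC evaluation. Includes a
    full-factorial trial-design generator, a synthetic-trial simulator
    with a solar-position utility, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml
Config/testthat/edition: 3
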