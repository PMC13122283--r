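Package: asps
Title: Abnormal Steroid Profile Scores for Longitudinal Urinary Steroid Ratios
Version: 0.1.0
Authors@R:
    person("ASPS", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for scoring longitudinal urinary steroid-ratio profiles from
    the steroidal module of the athlete biological passport. A Bayesian adaptive
    normal hierarchy on the log scale converts each new measurement of the five
    monitored ratios (T/E, A/Etio, 5a-ADiol/5b-ADiol, 5a-ADiol/E, A/T) into a
    sequence probability; whole-trajectory summary features feed a weighted
    logistic-regression classifier whose fitted probability is the abnormal
    steroid profile score (ASPS); the linear predictor is decomposed into
    per-biomarker source contributions with a flagging rule and false-positive
    rate threshold calibration. A synthetic cohort simulator with dose- and
    route-specific doping effects and washout makes the whole pipeline testable
    without access to doping-control data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
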