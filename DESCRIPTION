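Package: selfharmcosts
Title: Small-Area Incidence and Hospital Costs of Self-Harm Presentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates hospital-presenting self-harm incidence and associated
    general-hospital costs across small health-commissioning areas from
    sentinel-centre episode data. Implements age- and gender-specific rate
    estimation from a sentinel catchment, extrapolation to area populations,
    Gamma log-link cost regression with patient-clustered standard errors,
    cross-centre cost-model transfer with geographic price-index adjustment,
    Monte-Carlo propagation of cost-model uncertainty to percentile confidence
    intervals, and suicide-rate and rurality sensitivity calibrations. A
    synthetic episode and geography generator with known ground truth supports
    end-to-end testing without access to confidential patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    stats,
    sandwich,
    MASS,
    yaml,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
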