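Package: txbenefit
Title: Harm-Benefit Decomposition for Kidney Transplant Wait-List Eligibility
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-analytic model of deceased-donor kidney transplant
    wait-list eligibility. Models wait-list survival as exponential decline at
    a fixed mortality rate and post-transplant survival as a
    piecewise-constant relative-risk multiple of the wait-list hazard
    (increased, equivalent, then reduced risk). Computes the time to equal
    percent survival and the time to equal cumulative life years (restricted
    area-under-the-curve equality), decomposes a candidate's prognosis into
    probabilities of no benefit (death on the list), harm (transplanted but
    dead before the life-year break-even time), and benefit, adjusts
    relative risks for wait-list hold/inactive status, calibrates the
    relative-risk profile to published survival anchors, and validates the
    closed-form results with a Monte Carlo microsimulation of individual
    patient trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
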