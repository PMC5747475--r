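Package: waitlistMSM
Title: Multi-State Event-History Analysis of Kidney-Transplant Waitlist Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric multi-state modelling of kidney-transplant waitlist
    event histories. Candidates occupy one of twelve transient states defined by
    six calculated panel reactive antibody (CPRA) categories crossed with waitlist
    activity status (active/inactive), and exit into four absorbing outcomes
    (deceased-donor transplant, living-donor transplant, death or deterioration,
    other removal); direct transitions from inactive states to deceased-donor
    transplant are structurally excluded, giving 174 allowed transitions.
    Cumulative transition hazards are estimated by the Nelson-Aalen estimator and
    transition-probability matrices by the Aalen-Johansen product-integral
    estimator with Greenwood-type variances, supporting cross-sectional and
    dynamic prediction, dual censoring schemes around an allocation-policy
    change date, cohort demographic summaries with standardized differences,
    and a seeded piecewise-constant Markov cohort simulator with an exact
    matrix-exponential oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    cmprsk,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
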