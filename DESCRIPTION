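Package: ppcea
Title: Markov Cohort Cost-Utility Model of Pharmacopuncture for Chronic Low Back Pain
Version: 0.1.0
Authors@R: person("ppcea", "maintainers", email = "ppcea@example.org", role = c("aut", "cre"))
Description: A three-state (mild/moderate/severe pain) Markov cohort model
    comparing pharmacopuncture with physiotherapy for chronic low back pain
    over a 3-year horizon with 3-month cycles. Computes discounted costs and
    quality-adjusted life years under healthcare, restricted-societal and
    full-societal costing perspectives, incremental cost-effectiveness ratios
    with dominance classification, net monetary benefit, one-way deterministic
    sensitivity analysis (tornado ordering), and probabilistic sensitivity
    analysis with Beta/Gamma/Dirichlet parameter sampling and
    cost-effectiveness acceptability curves. Includes a synthetic-trial
    generator for parameter-recovery testing and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
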