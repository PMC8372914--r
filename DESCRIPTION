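Package: ubtcea
Title: Decision-Tree Cost-Effectiveness Analysis of Uterine Balloon
    Tamponade Devices for Atonic Post-Partum Hemorrhage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-analytic model comparing uterine balloon tamponade
    (UBT) devices (condom-UBT, ESM-UBT, Bakri-UBT) for the management of
    atonic post-partum hemorrhage in Indian public health facilities.
    Implements a chance-node decision-tree engine with expected-value
    cohort rollback, DALY (YLL + YLD) outcome valuation with configurable
    discounting, incremental cost-effectiveness (ICER) and net monetary
    benefit (NMB) analysis from societal and health-system perspectives,
    one-way (tornado) and probabilistic sensitivity analysis with
    Beta/Gamma parameter sampling, cost-effectiveness acceptability
    curves, and expected value of perfect information.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
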