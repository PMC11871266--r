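Package: ventcausal
Title: Causal Effects of Mechanical Power on Ventilation Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: DAG-guided causal analysis of mechanical power (MP) delivered by
    invasive mechanical ventilation. Computes MP and ventilator-free days at
    day 28 (VFD28) from hourly ventilator records, derives backdoor adjustment
    sets from a causal graph, estimates average and conditional average
    treatment effects by backdoor linear regression and cross-fitted double
    machine learning, fits hour-by-MP-threshold effect surfaces on the
    PaO2/FiO2 ratio, and simulates counterfactual optimal-MP trajectories
    under clinical noise. Ships a synthetic ICU cohort generator with known
    ground-truth effects so every stage is testable without access-gated
    clinical databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
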