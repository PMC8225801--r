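Package: cytoscreen
Title: Cost-Utility Modelling of Cytosponge-TFF3 Screening for Barrett Esophagus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-utility model for one-off Cytosponge-TFF3
    triage screening of gastro-esophageal reflux disease (GERD) patients versus
    usual care. Implements a two-chain (treatment vs natural-history) Markov
    cohort model of Barrett esophagus progression through to late-stage
    esophageal adenocarcinoma over a lifetime horizon with yearly cycles,
    half-cycle correction and discounting; screening-funnel cohort entry with
    test accuracy and uptake logic; incremental cost-effectiveness (ICER, net
    monetary benefit) and budget-impact analysis; probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves; one-way deterministic
    sensitivity analysis with tornado ordering; and a seeded synthetic
    screening-trial generator for end-to-end testing and parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
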