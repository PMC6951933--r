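Package: herdsim
Title: Stochastic Individual-Based Dairy Herd Life-Cycle Simulation and
    Least-Cost Ration Formulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A daily-time-step Monte-Carlo simulator of the dairy cow life
    cycle: calf generation with semen-type sex ratios, linear growth at breed
    average daily gain, an estrus-detection/artificial-insemination
    reproduction state machine (lognormal first-ovulation delay, normal cycle
    and gestation lengths, service-dependent conception, scheduled pregnancy
    diagnoses with window-specific daily pregnancy loss), Wood and MilkBot
    lactation curves, stochastic lifetime culling over six reasons with
    inverse-CDF culling-age sampling, and reproductive-failure culling rules.
    Includes a least-cost ration formulation option by linear programming over
    a user-supplied feed library and nutrient-requirement table, plus
    reproducible per-animal random-number substreams, event logging, and
    herd-level daily summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    yaml,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
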