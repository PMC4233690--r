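Package: incarcsim
Title: Agent-Based SIS Model of Contagious Incarceration on Synthetic
    Kinship Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates incarceration as a susceptible-incarcerated-susceptible
    (SIS) contagion on a synthetic multi-generational kinship and friendship
    network. Provides a demographic population generator (life-table mortality,
    fertility schedules, spatially matched friendships and partnerships),
    race-specific negative-binomial sentence-length distributions fitted to a
    target mean and median, relationship-typed monthly transmission
    probabilities derived from co-incarceration survey marginals, a monthly-step
    stochastic epidemic engine with ensemble replication, a non-contagious
    spontaneous-incarceration control model with rate tuning, recidivism
    statistics with cross-replicate simulation intervals, and closed-form SIS
    steady-state analysis with a critical sentence length.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
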