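Package: orthoflow
Title: Discrete-Event Simulation for Elective Orthopaedic Capacity Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A discrete-event simulation of a ring-fenced elective orthopaedic
    unit (operating theatres plus a finite ward bed pool) for capacity
    planning. Patients are booked into theatre sessions under configurable
    scheduling rules, lengths of stay are sampled from moment-matched
    lognormal distributions with stochastic routing of delayed discharges,
    and the model reports surgical throughput, per-weekday bed utilisation
    and theatre slots lost to bed shortages across grids of resourcing and
    productivity scenarios. Includes parameter fitting from electronic health
    record style spell data, a synthetic record generator, replication and
    scenario-sweep harnesses, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
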