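Package: antpatrol
Title: Agent-Based Simulation of Queen Patrol Feedback on Worker Reproduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Discrete-time agent-based model of a queen (gamergate) regulating
    worker reproduction in an ant colony through real-time contact feedback.
    Agents perform non-overlapping lattice random walks in a nest whose size
    scales with colony size at constant density; queen-worker contacts suppress
    a worker's internal state (a proxy for ovary development) while raising the
    queen's patrol propensity, which shortens her rest time. The package
    provides the state-update equations as pure functions, the spatial engine,
    a fast compiled trial runner, the full metrics suite (patrol frequency,
    rest time, contact rates, internal-state distributions), seeded experiment
    presets for colony-size sweeps, and deterministic fixtures for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
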