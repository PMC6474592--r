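Package: abxgame
Title: Evolutionary Game Theory of Antibiotic Prescribing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models antibiotic prescribing by doctors as a symmetric
    two-strategy population game and analyses it with the tools of
    classical and evolutionary game theory. Provides the payoff model
    (including scaled-resistance, residual-efficacy and efficacy-crossing
    variants), best-response and dominance analysis, symmetric Nash
    equilibria, evolutionarily stable strategy verification with an
    invasion-barrier estimate, replicator dynamics (trajectory
    integration, rest points with stability classification, vector
    fields, peak-velocity analysis), a tragedy-of-the-commons classifier,
    and a command-line interface emitting machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
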