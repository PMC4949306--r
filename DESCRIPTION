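Package: wlgame
Title: Winner-Loser Contest Games and Evolutionarily Stable Aggression Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a game-theoretical winner-loser model of dominance
    hierarchy formation. Individuals carry a resource holding potential (RHP)
    score that is multiplied up after a win and down after a loss, and fight
    whenever their RHP ratio to the opponent is at least their aggression
    threshold. The package provides the exact two-player analysis
    (threshold-to-concession-class mapping, dynamic-programming expected
    payoffs under a log-RHP and a resource-share payoff, first-passage
    stopping-time distributions), pure-ESS detection on payoff matrices via
    the diagonal rule, the V-C scaling law for thresholds, and a
    frequency-dependent evolutionary simulation that locates stable
    aggression thresholds in groups of N individuals. A small command-line
    interface exposes the main computations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
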