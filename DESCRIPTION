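Package: coopnet
Title: Donation-Game Dynamics on Directed Social Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how social networks emerge from individual
    cooperative actions. Implements the directed donation game in which a
    link records one participant paying a cost to provide a benefit to
    another, with up to two link updates per participant per round and two
    information treatments (providers hidden or visible). Provides an
    agent-based session simulator with inequity-averse link-update rules,
    network statistics (generosity/density, behavioural type L = (g-l)/(g+l),
    bidirectional-link reciprocity with a fixed-edge-count random-graph null,
    stationarity detection, recipient-provider Kendall correlation), and a
    link-update event analysis pipeline (delta-generosity/delta-payoff
    histograms, exact binomial preference tests, reciprocator splits),
    together with lossless session serialization and a small command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
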