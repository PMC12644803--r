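Package: ccforage
Title: Simulation and Analysis of a Dyadic Cooperation-Competition Foraging Game
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A game engine, synthetic dyad policies and an analysis pipeline for a
    continuous two-player foraging game in which a pair of agents collects
    winner-takes-all single targets and asymmetric joint targets on a square
    field. Provides deterministic-given-seed session simulation across the
    cooperation-competition spectrum (weighted path minimization, invitations,
    turn-taking, advantageous placement, skill asymmetries), session metrics
    (fraction-of-single-targets time courses, convergence, strategy groups), a
    multinomial softmax choice model with history and invitation predictors
    (cross-validated accuracy, AIC, prediction entropy, Wald and
    Benjamini-Hochberg inference), heuristic trajectory classification with
    Markov transition analysis, payoff decomposition into trajectory length and
    speed components, and counterfactual payoff models quantifying competitive
    skill differences and the cost of cooperation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
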