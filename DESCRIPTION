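Package: exoticnets
Title: How Exotic Plants Integrate into Plant-Pollinator Networks
Version: 0.1.0
Authors@R:
    person("Network", "Ecology Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the integration of exotic plant species
    into bipartite plant-pollinator mutualistic networks. Provides readers
    and validators for labelled interaction matrices with exotic-status
    annotations, NODF nestedness and connectance metrics, probabilistic
    (averaged-fill) and degree-preserving (checkerboard swap) null models,
    per-species nestedness contribution z-scores, phylogenetic diversity
    and uniqueness from dated plant phylogenies, quantitative
    interaction-level dependences and mass-action preferences, and the
    statistical layer that contrasts empirical networks against randomized
    ensembles with a mixed-effects logistic model of exotic-plant
    attachment. A synthetic-data module generates networks, phylogenies
    and multi-network study sets with planted structure so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    lme4,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
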