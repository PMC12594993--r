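Package: synthevolve
Title: Evolutionary Screening of Make-on-Demand Combinatorial Chemical Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Optimizes molecules inside reaction-defined (make-on-demand)
    combinatorial chemical spaces without enumerating them. Molecules are
    encoded as a reaction plus an ordered list of synthons, so every candidate
    the search visits is synthesizable by construction. Provides elitist,
    tournament and roulette selectors, similarity-guided fragment and reaction
    mutation, crossover, ligand-efficiency score normalization, a
    duplicate-similarity penalty, a pre-docked benchmark builder with greedy
    diversity selection, and hit-rate/enrichment-factor evaluation against a
    product-weighted random baseline. Fitness backends are pluggable: a
    pre-computed score table or a deterministic surrogate are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
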