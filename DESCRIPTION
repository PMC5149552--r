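Package: hipporl
Title: Hierarchical Model-Based Reinforcement Learning for Spatial Navigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tabular model-based reinforcement learning for grid-maze
    navigation with a hippocampus-inspired hierarchy of spatial abstractions.
    Provides deterministic grid-maze environments with ASCII I/O, smoothed
    transition/reward world models, prioritized-sweeping value updates under
    per-step budgets, cross-level goal selection with successive A* plan
    refinement, likelihood-based context detection with policy remapping,
    simulated dorsal/ventral hippocampal lesions, and drivers for the four
    simulation experiments (lesion, boundary adaptation, probabilistic reward
    contexts, and scaling), with reproducible seeding throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tibble
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RcppModules: hipporl_module
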