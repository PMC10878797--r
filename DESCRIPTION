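Package: neutralherb
Title: Neutral Compound-Poisson Models of Herbivore Damage Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling the distribution of proportion herbivore
    damage among leaves and plants as a neutral stochastic process: a
    truncated compound Poisson process whose per-event damage follows a
    truncated Pareto distribution with an exponent derived from metabolic
    scaling.  Provides maximum-likelihood estimation of the herbivore
    attack rate, large-attack-rate normal-limit approximations of
    inequality indices (CV, Gini, Hoover), phenomenological competitor
    distributions (hurdle truncated lognormal and zero-one-inflated beta)
    with AICc model selection, observed-versus-predicted diagnostics
    (Monte-Carlo-averaged Kolmogorov-Smirnov tests, ten statistical
    probes with a constrained variance partition, major-axis CV
    regression, leaf-shuffle permutation nulls, bootstrapped
    Kullback-Leibler divergence), and a synthetic survey generator
    emulating standardized herbivory surveys with optional non-neutral
    structure.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
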