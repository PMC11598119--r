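Package: slopt
Title: Snow Leopard Optimization for Continuous Problems and High-Dimensional Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements snow leopard optimization (SLO), a population
    metaheuristic whose four behavioral phases (territory delineation,
    neighborhood relocation toward peers or the incumbent best, and territorial
    disputes) are gated by a deterministic temperature schedule. Includes a
    wrapper feature-selection protocol for high-dimensional labeled expression
    tables (continuous solutions binarized at 0.5, fitness combining KNN
    accuracy under stratified K-fold cross-validation with a feature-count
    penalty), a suite of classical continuous benchmark functions with a
    mean-error repetition protocol, a generator of synthetic expression-like
    datasets with planted informative features, Friedman average-rank
    comparison of score tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    class
Config/testthat/edition: 3
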