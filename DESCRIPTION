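Package: mintr
Title: Predicting Nutrient Density of Food Items from Menu Text
Version: 0.1.0
Authors@R:
    person("MINT", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the nutrient density of food items from
    their names alone. Implements the RRR (ratio of recommended to
    restricted nutrients) and RRRmacro indices with FDA daily values,
    trains subword-aware food-language word embeddings on recipe-style
    corpora, derives food-category pseudo-labels by reducing
    ingredient-contextualized embeddings to two dimensions and
    soft-clustering them, fits category-routed five-layer neural
    regressors with Monte Carlo dropout confidence intervals, and
    aggregates item predictions into restaurant- and region-level
    nutrient density scores. Includes a seeded synthetic data generator
    emulating generic-food-item databases so the full pipeline is
    testable without licensed data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    uwot,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
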