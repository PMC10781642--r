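Package: altrix
Title: Phylogenetic Analysis of Mammalian Altriciality and the Timing of
    Neurodevelopment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative tools for studying how altricial development evolved
    across placental mammals. Implements a variable-rates Brownian-motion model
    (branch-specific rate scalars inferred by reversible-jump MCMC), ancestral
    state reconstruction, signed branch-specific evolutionary-rate ratios on
    generation-scaled phylogenies, phylogenetic generalized least squares
    (PGLS) allometry of neonatal versus adult brain and body size with
    generalized phylogenetic ANCOVA, a translating-time neurodevelopmental
    clock applied to fossil hominins, group comparisons of brain and body
    proportions at birth, and a fully seeded synthetic-data generator so the
    whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
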