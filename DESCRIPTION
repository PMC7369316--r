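Package: omapop
Title: Population Analysis of Format-Dependent Encoding of Observed
    Manipulative Actions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end single-unit and population analysis of spiking
    responses to videos of observed manipulative actions (OMAs) presented in
    multiple visual formats: ANOVA-based unit classification, additive versus
    multiplicative format-by-action mixing models with split-half
    cross-validation, Poisson naive Bayes pseudopopulation decoding with
    temporal generalization and permutation nulls, an across-format rank
    stability index with shuffled and constrained-shuffled nulls, and
    Mahalanobis-distance hierarchical clustering of condition means in neural
    state space. Includes a ground-truth-labelled synthetic Poisson
    spike-train generator emulating the 7-exemplar by 4-format design, so
    every stage is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
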