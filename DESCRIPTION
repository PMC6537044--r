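Package: anchorscreen
Title: Anchored Drug-Screen Analysis, Dose-Response and Combination Synergy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for anchor-compound drug screens in multiwell
    plates: log transformation and B-score positional normalization (two-way
    median polish), robust Z-score (RZ) hit calling with a replicate-concordance
    rule, delta-RZ ranking of anchor-potentiated compounds, four-parameter
    logistic dose-response fitting with IC50-based sensitivity classification,
    two-drug combination scoring by Loewe-additivity excess and Chou-Talalay
    combination index, and in-vivo tumor-growth analytics (relative tumor
    volume, tumor growth inhibition, Mann-Whitney tests, Fisher-exact cell-cycle
    comparisons with Benjamini-Hochberg adjustment). Includes seeded synthetic
    data generators with planted ground truth for every input the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
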