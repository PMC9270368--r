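Package: morphoverlap
Title: Morphological Overlap and Hybrid Contribution in Cryptic Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies morphological overlap between cryptic species in
    sympatry and the contribution of hybrids to that overlap. Provides a
    validated per-individual trait table (wing and dentition morphometry in
    mm plus dorsal/ventral CIELAB colour), a calibrated synthetic cohort
    generator for the five-group allopatry/sympatry/hybrid design,
    group-comparison statistics (tie-corrected Kruskal-Wallis, one-way
    ANOVA, Fisher's LSD and Tukey HSD post hocs, Box's M, permutation and
    classical MANOVA), correlation-matrix PCA summaries with Kaiser
    retention and Cronbach's alpha, two classification engines (stepwise
    Wilks' lambda discriminant analysis with leave-one-out quadratic
    classification, and a radial-kernel SVM ensemble with a single-claim
    acceptance rule), and the overlap and hybrid-contribution statistics
    with their cross-method aggregation and comparison tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
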