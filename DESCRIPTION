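Package: hetmap
Title: Macrogenetic Mapping of Observed Heterozygosity from Gridded
    Anthropogenic Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for macrogenetic analyses that relate
    observed heterozygosity (Ho) of sampled populations to gridded
    anthropogenic predictors. Provides locality-table validation,
    harmonization of predictor rasters onto a common geographic grid with
    nearest-neighbour resampling, complete-case point extraction, Pearson
    correlation screening, principal component analysis with hierarchical
    clustering on component scores, island-versus-mainland rank-sum
    comparisons, random-forest regression with an out-of-bag RMSE grid
    search over forest sizes, jackknife (leave-one-out) validation,
    max-normalized impurity (Gini) importance, a from-scratch Multivariate
    Environmental Similarity Surface (MESS) with a median-of-positives
    validity mask, and masked worldwide projection of predicted Ho. A
    synthetic-data generator with known effect structure makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
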