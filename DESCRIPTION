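Package: urbfilter
Title: Nonrandom Species Filtering and Distance-Based Analysis of Urban
    Bird Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to test whether species losses along an
    urbanization gradient are random. Implements a multinomial
    resampling null model that classifies urban absences as
    chance-absent or urban-avoider from a periurban source pool,
    permutational multivariate analysis of covariance (PERMANCOVA)
    on arbitrary dissimilarity matrices with mixed-model
    denominators, Monte-Carlo p-values and components of variation,
    similarity-percentage (SIMPER) decomposition of Bray-Curtis
    dissimilarity, principal coordinates analysis with
    centroid-level distance matrices and correlation vector
    overlays, and a synthetic point-count survey generator with
    known ground-truth filtering for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    ape,
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
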