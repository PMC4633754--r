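Package: mediarec
Title: Culture-Media Recipe Compilation and Growth-Media Recommendation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compiles semi-structured microbial culture-media recipes into
    standardized molar compositions (unit normalization, hydrate-aware
    gram-to-mole conversion, recursive unpacking of submedium
    cross-references, fill/scale volume resolution) and predicts new
    organism-media pairings from a positive-only growth database.
    Predictors include transitive-relation mining with a binomial
    significance test, phylogeny- or ecology-weighted collaborative
    filtering with salt and oxygen compatibility filters, and media
    richness preference scoring.  A synthetic-data generator with
    tunable phylogenetic signal makes every predictor testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
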