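Package: ecazones
Title: Management-Zone Delineation and Validation from Soil Apparent
    Electrical Conductivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delineating and validating vineyard management zones
    from proximal soil sensing. Implements experimental variograms and
    spherical-model fitting, ordinary kriging with a local neighbourhood and
    leave-one-out diagnostics, ISODATA-style clustering of standardized ECa
    and elevation rasters followed by maximum-likelihood classification,
    fusion of soil-property tables into a latent soil-fertility measure via
    the polytomous Rasch rating-scale model fitted by joint maximum
    likelihood (with Infit/Outfit mean-square diagnostics), and zone
    validation with Kruskal-Wallis and Dunn tests with compact letter
    displays. A synthetic-data module generates Gaussian random fields,
    transect surveys, digital elevation models and rating-scale responses
    with stored ground truth so every stage is testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
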