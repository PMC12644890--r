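Package: microsucc
Title: Soil Microbial Diversity, Niche Overlap and Functional Redundancy
    Along Land-Abandonment Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for paired-site studies of soil microbial
    communities along grassland-to-forest succession gradients. Provides
    feature-table input/output and validation, scaling-with-ranked-subsampling
    (SRS) and rarefaction normalization, alpha/beta diversity with
    permutational multivariate tests and paired effect sizes (partial
    omega-squared, Hedges' g), Levin's niche breadth and overlap of
    nutrient-cycling gene families with limit-of-quantification filtering,
    the ternary decomposition of diversity into Simpson dominance, Rao's
    quadratic entropy and functional redundancy, substrate-induced
    respiration (MSIR) processing, hierarchical partitioning of regression
    predictors, and a synthetic paired-site data generator with ground truth
    for end-to-end recovery testing.
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
    tools,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
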