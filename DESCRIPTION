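Package: caretraj
Title: Typologies of Healthcare Utilization Trajectories by Multichannel
    Sequence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to derive typologies of longitudinal healthcare
    utilization from annual categorical states observed in parallel across
    five service channels (ambulatory care, emergency care, hospitalization,
    professional home care, nursing home stay). Implements multichannel
    Optimal Matching dissimilarities with explicit modelling of death,
    incapacity and random nonresponse states, dissimilarity-based clustering
    with average-silhouette and minimum-cluster-size model selection, and
    cluster characterization through bivariate tests and multinomial
    logistic regression with backward stepwise AIC selection. Includes a
    seeded synthetic cohort generator with latent trajectory archetypes so
    the full pipeline can be exercised and tested without access to
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
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
    mclust,
    nnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
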