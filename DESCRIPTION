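Package: commstruct
Title: Community Phylogenetic and Functional Structure of Bird Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analytical pipeline for community ecology of resident passerine
    birds: taxonomic, phylogenetic (Faith's PD) and dendrogram-based functional
    diversity; mean pairwise phylogenetic/functional distances with
    randomization-null standardized effect sizes (SESmpd, SESmfd); phylogenetic
    signal tests (Blomberg's K, Fritz-Purvis D); spatially explicit regression
    (standardized OLS, Moran's I residual diagnostics, maximum-likelihood
    spatial-error SAR, VIF screening); piecewise structural equation models
    with d-separation tests and Fisher's C; and a synthetic-study generator
    (Yule trees, Brownian traits, community assembly under filtering or
    competition, spatially autocorrelated site covariates) so that every stage
    is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    cluster,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
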