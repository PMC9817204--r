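Package: phyloscape
Title: Spatial Phylogenetic Diversity, Endemism and Their Environmental Drivers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gridded spatial-phylogenetics toolkit: Faith's phylogenetic
    diversity (PD), Rosauer's phylogenetic endemism (PE) and weighted
    endemism on a regular grid of communities; tip-shuffle and fixed-fixed
    (independent swap) permutation null models with standardized effect
    sizes; terrain indices (slope, TPI, TRI) from a digital elevation model;
    a PCA-based climatic-instability statistic over paleoclimate time
    series; collinearity screening by correlation clustering and stepwise
    variance-inflation-factor removal; Moran's I correlograms,
    distance-band spatial weights, maximum-likelihood spatial-error
    autoregressive models with exhaustive-subset AIC selection and
    Nagelkerke pseudo R-squared; and a synthetic-data generator (Yule
    trees, Gaussian random field environments, quantile-thresholded
    species ranges, random-walk paleoclimate series) with known ground
    truth for end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
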