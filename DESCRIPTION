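Package: smfnet
Title: Soil Multifunctionality and Aggregate-Scale Microbial Co-Occurrence Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An aggregate-scale analysis pipeline linking soil microbial
    community structure to soil multifunctionality (SMF). Provides composite
    SMF scoring from min-max standardized carbon, nitrogen and phosphorus
    cycle indicators; alpha diversity, Bray-Curtis dissimilarity and
    nonmetric multidimensional scaling; Spearman co-occurrence network
    inference per vegetation-by-aggregate stratum with the six standard
    topological parameters and an ensemble-standardized network complexity
    index; fixed-effects hierarchical partitioning of variance over a
    two-factor design; partial least squares path modeling with
    goodness-of-fit and effect decomposition; and a synthetic-data generator
    with planted ground truth for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
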