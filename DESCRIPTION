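Package: soilionet
Title: Ordination, Variance Partitioning, Effect Sizes and Co-Occurrence
    Networks for Soil Ionome and Enzyme Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical analysis chain for long-term soil fertilization
    trials measuring exchangeable ion concentrations and extracellular
    enzyme activities across sites and fertilization treatments.
    Provides Bray-Curtis dissimilarities with nonmetric multidimensional
    scaling (Kruskal stress-1, Shepard diagnostics), variance
    partitioning of Hellinger-transformed profiles among pH, site and
    fertilization by adjusted-R2 redundancy analysis with permutation
    tests, weighted natural-log response ratios of organic versus
    mineral fertilization with sampling-variance confidence intervals,
    and thresholded Pearson co-occurrence networks between ions and
    enzymes with community detection and Gephi-compatible export.  A
    seeded synthetic-data generator emulating the 2-treatment x
    4-site x 3-replicate design, with planted effect sizes and
    correlation blocks, supports end-to-end testing and parameter
    recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
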