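Package: germcore
Title: Germplasm Characterization and Core Collection Construction for
    Augmented Block Design Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the complete phenotypic characterization and core
    collection workflow used with large genebank collections evaluated in
    Federer's augmented randomized complete block design (ABD): block-adjusted
    entry means, augmented-design ANOVA with critical differences and
    promising-accession calls, genetic variability parameters (GCV, PCV,
    broad-sense heritability, genetic advance and gain) with their
    conventional categories, Gower distances on mixed quantitative and
    qualitative descriptor data, five core-subset sampling strategies
    (entry-to-nearest-entry and accession-to-nearest-entry weighted local
    search, PowerCore-style greedy class coverage, principal component score
    selection) with forced-inclusion and geographic-coverage constraints, and
    the full battery of core-versus-collection quality indices (MD%, VD%,
    CR%, VR%, class coverage, Shannon diversity and evenness, sign tests,
    Mantel test, and two-sample distribution comparisons). A synthetic
    collection generator with known genotypic truth supports validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    cluster,
    MASS,
    car,
    ape,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
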