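Package: micronet
Title: Co-Occurrence Networks and Nitrogen-Use Statistics for Soil
    Amendment Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis chain for soil amendment incubation and pot
    experiments that profile the bacterial community with 16S amplicon
    count tables. Provides rarefaction, Good's coverage, taxonomic
    aggregation and abundance filtering; Bray-Curtis ordination (PCoA)
    with ANOSIM; signed Spearman co-occurrence networks with
    false-discovery-rate control and a random-matrix-theory threshold
    scan based on the nearest-neighbour eigenvalue spacing distribution;
    modularity-based module detection with per-sample module abundances;
    module-environment correlation, per-taxon enrichment calls for
    Manhattan plots, and (partial) Mantel tests for functional guilds;
    nitrogen use, agronomic and physiological efficiency statistics with
    one-way ANOVA and Duncan's multiple-range letter displays; and a
    seeded synthetic-data generator with known ground truth so the whole
    chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
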