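Package: metapom
Title: Metabolic-Network Organization of Molecular Odor Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking metabolic-network structure to
    distances in molecular representation spaces such as a principal odor
    map (POM). Provides SMILES standardization and circular fingerprints,
    directed metabolite graphs with shortest-path metabolic distance,
    stratified odorant-pair sampling, metabolic-distance versus
    representation-distance correlation, PCA-based pathway smoothness
    statistics, essential-oil co-occurrence rank-shift statistics,
    cross-validated performance-index benchmarking, trial-resolved neural
    response extraction, and seeded synthetic-data generators that emulate
    the statistical structure of each input so the whole pipeline runs at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    igraph,
    jsonlite,
    ranger,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
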