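Package: eoscreen
Title: Consensus Virtual-Screening Post-Processing and Essential-Oil Target Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processes multi-function molecular docking score tables into
    archetypal chemical clusters of strong insecticide-target binders, a binary
    compound-to-target likelihood matrix, and predicted target-action profiles
    for whole essential oils from their gas-chromatographic composition.
    Includes enrichment-factor and ROC validation of scoring functions against
    active/decoy benchmarks, successive k-means consensus hit selection,
    Tanimoto-distance hierarchical clustering of chemical archetypes,
    z-scored descriptor-space proximity and fuzzy Tanimoto membership matrices,
    a cosine-distance larval motility statistic for binarized video frame
    stacks, and seeded synthetic-data generators for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    igraph,
    jsonlite,
    png,
    ape,
    EBImage,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ChemmineOB,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
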