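Package: adaptscape
Title: Landscape Genomics of Local Adaptation and Genetic Offset
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested landscape-genomics pipeline for diploid SNP data:
    population-structure statistics (Weir-Cockerham F_ST, genotype PCA, Nei
    distance, neighbor joining, PERMANOVA, folded site-frequency-spectrum
    projection), genotype-environment association scanning (ridge latent
    factor mixed models and a principal-component outlier scan with
    Benjamini-Hochberg control), competition of isolation-by-distance,
    -environment and -resistance hypotheses (Mantel and partial Mantel tests,
    reciprocal causal modeling, maximum-likelihood population-effects models,
    PCNM spatial eigenvectors, three-set partial-RDA variance partitioning),
    and three genetic-offset estimators under climate-change scenarios (risk
    of non-adaptedness, gradient-forest turnover offsets, and generalized
    dissimilarity model local, forward and reverse offsets with migration
    distance and bearing). A synthetic-data generator with recorded ground
    truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    vegan,
    geosphere,
    pracma,
    vcfR,
    jsonlite,
    randomForest
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
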