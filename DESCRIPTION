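Package: pleioscan
Title: Selection Scans, Trans-eQTL Mapping, Co-Expression Connectivity and
    Pleiotropy Simulations for Local-Adaptation Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to test whether candidate loci for local adaptation are
    unusually pleiotropic, using network connectivity as a phenotype-free proxy.
    Implements per-gene diversity and neutrality statistics (theta-pi, Watterson's
    theta, Tajima's D, normalized Fay and Wu's H, Hudson's FST, dXY), a
    SweepFinder-style composite likelihood ratio sweep scan against the
    transcriptome-wide site frequency spectrum, PCA-differentiation and
    environmental-association outlier scans with Storey q-values, all-pairs
    trans-eQTL mapping with admixture covariates, signed weighted co-expression
    networks (soft-threshold adjacency, topological overlap, module detection,
    connectivity), enrichment and permutation-based integration statistics, and a
    forward Wright-Fisher simulation of a pleiotropic QTL region adapting to a
    displaced phenotypic optimum. A seeded synthetic-data generator with a
    machine-readable truth set makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    mgcv,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
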