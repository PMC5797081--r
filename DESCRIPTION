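Package: methclust
Title: Differential Methylation Clusters and Cross-Species Conservation for
    MeDIP-seq Count Data
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of MeDIP-seq methylation peak counts:
    trimmed-mean-of-M-values normalization, differential methylation testing
    in a discordant monozygotic twin design (per-pair log fold changes,
    optionally moderated one-sample tests, and a discordant-versus-concordant
    one-tailed Wilcoxon contrast) and in a two-group animal design (negative
    binomial generalized linear models with an immunoprecipitation-pool
    covariate), density-based clustering of methylated regions along the
    genome into clusters containing significant regions (ccDMRs),
    cluster-debiased Gene Ontology enrichment with geometric-mean-rank
    scoring and empirical p-values, chromatin-state and repeat-class
    enrichment with per-cluster z-score profiles, and conserved-cluster
    detection across assemblies through a block map with a minimum
    mapped-fraction rule. A seeded synthetic-data generator emulating the
    count structure of such studies makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    limma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
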