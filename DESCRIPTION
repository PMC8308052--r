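Package: circStrata
Title: Sample Stratification by Circular RNA Expression and Gene Expression Impact
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of circular RNA (circRNA) and linear gene
    expression from bulk RNA-seq read counts. Samples are grouped in an
    unsupervised fashion by each circRNA's back-splice junction expression
    (median split or silhouette-guided clustering), circRNAs whose expression
    discriminates the groups are selected with negative-binomial Wald tests or
    one-way ANOVA, ranked by their contribution to the leading principal
    components, and each selected circRNA's downstream impact on the
    transcriptome is characterized by negative-binomial differential gene
    expression, random-forest classification with recursive feature
    elimination, and preranked gene set enrichment analysis. A seeded
    negative-binomial simulator with planted circRNA-gene links supports
    method validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    DESeq2,
    MASS,
    cluster,
    caret,
    randomForest,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    fgsea
biocViews: Transcriptomics, RNASeq, DifferentialExpression, Clustering,
    PrincipalComponent, GeneSetEnrichment, Classification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
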