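Package: ncqtlnet
Title: Association Networks from Non-Coding-RNA-Linked eQTL
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for uncovering clinically relevant
    association networks from genetic variants linked to non-coding RNAs.
    Catalogs SNPs overlapping miRNA seeds, miRNA-binding sites and
    length-filtered lincRNA genes; runs a Spearman eQTL scan with
    Benjamini-Hochberg correction; computes pairwise linkage-disequilibrium
    R-squared from unphased dosages; joins significant eQTL to clinical and
    pharmacogenomic annotation catalogs directly by rsid and indirectly via
    high-LD proxies; builds typed multi-graph association networks over SNP,
    gene, miRNA/lincRNA and phenotype nodes; and measures network robustness
    by iterative eQTL knockout. Includes a seeded synthetic-cohort generator
    (block-LD genotypes, planted cis-effects, feature intervals, annotation
    catalogs) so the whole workflow is testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
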