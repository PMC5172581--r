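Package: fpibd
Title: Identity-by-Descent Segment Discovery in Foundation-Parent Maize Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects identity-by-descent (IBD) segments shared within
    descendant groups of maize foundation parents from SNP genotype panels,
    using a zero-diversity tag-locus window scan of Nei gene diversity with a
    per-chromosome threshold. Partitions segments into group-specific and
    shared classes, co-localizes them with mixed-linear-model GWAS
    quantitative trait nucleotides and literature QTL intervals, and
    nominates candidate genes by physical linkage to tag SNPs and
    group-differential expression. Includes population-structure tools
    (identity-by-state distance, UPGMA cladogram, PCA, diversity-covering
    subset selection), multi-environment BLUP phenotype summaries, and a
    founder-descendant panel simulator with planted truth for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    ape,
    phangorn,
    lme4,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    multcomp
Config/testthat/edition: 3
biocViews: Genetics, SNP, GenomeWideAssociationStudy, Clustering,
    GeneExpression
RoxygenNote: 7.3.3
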