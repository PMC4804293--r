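Package: cnvpopgen
Title: Population Genetics of Copy Number Variation from SNP Array Log R Ratios
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for copy-number-variation (CNV) based population
    genetics on SNP-array intensity data. Starting from probe-by-sample log R ratio
    (LRR) matrices, the package removes GC-content intensity waves, partitions
    chromosomes into multi-sample least-squares segments with permutation-tested
    breakpoints, genotypes segments under a three-state (loss/neutral/gain) model,
    merges calls into non-redundant CNV regions, and recodes deletion CNVs as
    biallelic markers. Downstream it provides identity-by-state genetic distances,
    classical multidimensional scaling, neighbor-joining trees, hierarchical
    clustering of segment-mean profiles, maximum-likelihood admixture inference, and
    Vst scans for lineage-differentiated CNV regions with gene-overlap annotation.
    A synthetic-cohort generator with known truth (hierarchically diverged breeds,
    hybrid individuals, group-differentiated deletion loci, GC waves) makes every
    stage testable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    ape,
    rtracklayer,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: CopyNumberVariation, SNP, PopulationGenetics, Clustering
RoxygenNote: 7.3.3
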