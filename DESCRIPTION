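Package: morphoqtl
Title: Cell Morphological QTL Mapping from Image-Based Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for mapping genetic determinants
    of single-cell morphology (cell morphological QTLs, cmQTLs). Starting from
    CellProfiler-style single-cell feature tables and donor genotypes, the
    package performs cell- and trait-level quality control, colony/isolate
    context splitting, well-level aggregation, rank-based inverse normal
    transformation, greedy composite-trait selection, linear mixed-model
    variance decomposition, genotype QC with an exact Hardy-Weinberg test,
    LD pruning, genetic relatedness matrix construction and ancestry PCA,
    gene-level rare-variant burden collapsing, rare and common variant
    association scans with permutation nulls and genomic-inflation
    diagnostics, and a Gaussian scale-mixture model of standardized effect
    sizes used to project discovery counts at larger sample sizes. A
    synthetic-data generator with known variance structure and planted
    genetic effects provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
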