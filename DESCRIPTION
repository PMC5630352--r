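Package: bivalency
Title: Bivalent Chromatin Transition Classification and Downstream Statistics
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies gene promoters into bivalency transition groups
    (I-IV) from H3K4me3 and H3K27me3 peak calls obtained in two cellular
    conditions (e.g. epithelial versus mesenchymal), and provides the
    downstream statistics used in bivalency studies: gene-set overlap by
    Fisher's exact test with odds ratios, term enrichment in two-list
    hypergeometric and ranked minimum-hypergeometric (mHG) modes, group-wise
    expression repression summaries with exact Mann-Whitney tests, cohort
    gene-set scoring with triple-negative receptor labeling and Welch tests,
    and deterministic qPCR / ChIP-qPCR calculators (2^-ddCt, percent input,
    H3-normalized enrichment, Holm-Sidak correction, three-criterion
    MET-reactivation calls). Includes a synthetic-data generator with planted
    ground truth for every pipeline stage and a configuration-driven
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    data.table,
    S4Vectors,
    digest,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
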