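Package: wgmsQC
Title: Quality-Control Metrics and Read Simulation for Whole-Genome
    Methylation Sequencing Library Protocols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative evaluation of whole-genome methylation sequencing
    (WGMS) library-preparation protocols: raw-read base-quality binning,
    alignment-quality fractions, insert-size summaries, duplicate rate and
    library-complexity curves, mappability-weighted observed/expected coverage
    uniformity, CpG coverage per genomic element category, context-stratified
    cytosine retention, M-bias profiles, spike-in conversion controls,
    100-kb binned beta values with Spearman replicate concordance,
    smoothed-M-value PCA, and a two-replicate cross-protocol bias test.
    Includes a synthetic WGMS data generator (directional and PBAT strand
    conventions, conversion failure and over-conversion, CpG-island coverage
    bias, M-bias, duplication, unmethylated lambda-like and methylated
    pUC19-like spike-in contigs) so every metric is verifiable by parameter
    recovery at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
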