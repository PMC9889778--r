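Package: fibroscape
Title: Fibroblast Heterogeneity Analysis for Single-Cell and Bulk Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting fibroblast heterogeneity in lung tissue from
    single-cell and bulk transcriptomic data. Implements gene-module scoring
    with expression-matched control genes, signature-based demarcation of
    fibroblasts from mural cells, a k-nearest-neighbour overlap z-score for
    batch-effect detection, sample-level marker discovery with a clustering
    resolution sweep, diffusion-map pseudotime with cross-dataset Stouffer
    meta-analysis and consensus gene modules, signature-matrix deconvolution
    benchmarking on simulated pseudobulk mixtures, maximally selected log-rank
    cutpoint survival stratification, and histo-cytometry classification rules
    for multiplexed immunohistochemistry. Includes synthetic-data generators
    emulating the statistical structure each stage assumes, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    pracma,
    stats,
    survival,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
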