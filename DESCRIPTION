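Package: orfscreen
Title: Analysis of ORF-Overexpression Transcriptomic Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end analysis of expression-based functional screens in
    which open reading frames (ORFs) are overexpressed in a cell line and
    their transcriptomic effects read out on one or two microarray
    platforms. Implements per-platform normalization (normexp background
    correction, cyclic loess, quantile normalization with offset),
    location/scale empirical-Bayes batch adjustment, intensity flooring,
    a robust median/MAD Z-score HIT statistic with gene-level roll-up,
    empty-vector resampling to estimate the false-positive HIT rate,
    cross-platform gene-level effect merging, asymmetric ORF-similarity
    scoring with a thresholded directed network and an averaged t-SNE
    embedding, hypergeometric gene-set over-representation of HIT lists,
    and the small validation statistics used for follow-up experiments
    (exact separation test, geometric-mean/SEM intervals, qPCR
    normalization). A synthetic screen generator with planted effect
    structure supports testing every stage against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    limma,
    igraph,
    vegan,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
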