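Package: translevel
Title: Two-Level Transcriptional and Translational Expression Analysis
    from Polysome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the joint analysis of gene expression regulation at
    the transcriptional and translational level from paired total-RNA and
    polysome-fraction RNA-seq count matrices. Implements negative-binomial
    differential expression with moment-shrinkage dispersion estimation,
    the translational ratio (log2 polysome/total) and its between-condition
    difference with an interaction-based differential-translation test,
    Up/Down/Stable gene classification, UpSet-style exclusive set
    intersections and Jaccard comparison of gene-set collections,
    self-contained weighted co-expression network analysis (soft-threshold
    selection, topological overlap, module detection, eigengenes,
    module-trait correlation, hub genes), cross-level module overlap with
    hypergeometric significance, offline over/under-representation analysis
    against GMT annotations, closed-form wet-lab calculations (electrolyte
    leakage, delta-delta-Ct), and a synthetic-data generator with planted
    regulatory programs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    grid,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    mclust,
    pheatmap,
    edgeR,
    optparse
Config/testthat/edition: 3
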