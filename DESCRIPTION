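Package: tidyexpr
Title: Tidy Grammar for Bulk Transcript Abundance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular tidy framework for bulk RNA-seq analysis built around a
    long-format expression table with registered key columns and a hidden
    internals store. A self-explanatory verb grammar (scale, filter, adjust,
    reduce, cluster, deconvolve, test) operates on the table, every verb
    supporting the add/get/only action modes. All backend algorithms are
    implemented natively: trimmed-mean-of-M-values (TMM) scaling factors,
    voom precision weights with empirical-Bayes moderated t-statistics, a
    negative-binomial likelihood-ratio engine, empirical-Bayes location/scale
    batch adjustment, classical multidimensional scaling on leading
    log-fold-change distances, principal components, k-means++ and
    shared-nearest-neighbour/Louvain clustering, greedy redundancy removal,
    and signature-based cell-type deconvolution by non-negative least squares.
    Seeded negative-binomial and mixture simulators make every stage testable
    without external data, and a chainable command-line interface mirrors the
    in-process verb pipeline over long-format TSV streams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    stats,
    utils,
    methods,
    Matrix,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Rtsne,
    fgsea,
    edgeR,
    limma,
    sva,
    mclust,
    igraph,
    withr,
    jsonlite
Config/testthat/edition: 3
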