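Package: reprogscore
Title: Reprogramming-Completeness Scoring for iPS Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores how completely induced pluripotent stem (iPS) cell lines
    have been reprogrammed from their somatic cells of origin, using bulk
    RNA-seq counts. Provides a self-contained negative-binomial
    differential-expression engine (median-of-ratios size factors,
    method-of-moments dispersions, Wald tests with Benjamini-Hochberg
    adjustment), a four-way per-gene classifier (correctly reprogrammed,
    intermediate, not reprogrammed, novel) over the fibroblast-versus-ES
    signature gene set with cross-line intersection reports, exploratory
    clustering/PCA/heat-map utilities, and a negative-binomial count
    simulator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse,
    withr
Config/testthat/edition: 3
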