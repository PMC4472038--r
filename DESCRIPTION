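Package: tissueid
Type: Package
Title: Tissue Identity Scoring of Transcriptomes Against a Labelled Reference Atlas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores bulk RNA-seq or microarray samples against a labelled
    reference expression atlas. Classifier genes are selected by 10-fold
    cross-validated multinomial LASSO over the most variably expressed
    reference genes that are also measured in the query, and every query
    sample receives per-class identity scores (multinomial probabilities
    summing to one). Supporting steps cover detection filtering, TMM and
    counts-per-million normalization, housekeeping-gene scaling of microarray
    intensities onto the sequencing scale, classifier-gene barcode summaries,
    correlation-based hierarchical clustering, stage-specific gene partitions,
    and a negative-binomial count simulator with planted tissue markers for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
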