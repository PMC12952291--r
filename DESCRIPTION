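Package: geosift
Title: Semantic and Frequency-Based Retrieval of Gene-Expression Series Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for finding transcriptomic data series by the similarity of
    their free-text descriptions. Reads GEO-style series metadata (JSON-lines or
    a SOFT subset), filters and cleans it, and ranks candidate series against a
    reference set of known-relevant series using word-overlap (Jaccard), the
    lucene variant of BM25, a deterministic hashed TF-IDF embedder, or externally
    computed embedding vectors, with optional chunk-and-average aggregation for
    long texts. Includes the full retrieval benchmark protocol (per-condition
    reference/comparison splits, average-precision AUPRC, recall at n,
    class-imbalance subsampling, cross-condition median-rank aggregation), a
    synthetic labelled-corpus generator with controllable condition-vocabulary
    overlap, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
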