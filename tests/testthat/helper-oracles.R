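# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths: the AP oracle loops over explicit prefix counts,
# the BM25 oracle evaluates the closed form term by term from raw token
# lists, and the random-ranking expectation comes from the
# negative-hypergeometric closed form.

# Average precision by explicit enumeration: precision@k recomputed by
# counting from scratch at the rank of each relevant item.
ap_bruteforce <- function(labels) {
  stopifnot(any(labels), !all(labels))
  total <- 0
  n_rel <- 0
  for (k in seq_along(labels)) {
    if (labels[k]) {
      hits <- 0
      for (j in 1:k) if (labels[j]) hits <- hits + 1
      total <- total + hits / k
      n_rel <- n_rel + 1
    }
  }
  total / n_rel
}

# Lucene-variant BM25 straight from the formula, from raw token lists.
bm25_bruteforce <- function(docs_tokens, query_tokens, doc_index, k1, b) {
  n <- length(docs_tokens)
  avgdl <- mean(vapply(docs_tokens, length, integer(1)))
  d <- docs_tokens[[doc_index]]
  score <- 0
  for (t in query_tokens) {
    df <- sum(vapply(docs_tokens, function(x) t %in% x, logical(1)))
    idf <- log(1 + (n - df + 0.5) / (df + 0.5))
    f <- sum(d == t)
    score <- score + idf * f / (f + k1 * (1 - b + b * length(d) / avgdl))
  }
  score
}

# Exact E[average precision] under a uniformly random ranking of R relevant
# items among n, via the negative-hypergeometric rank distribution of the
# j-th relevant item.
expected_ap_random <- function(n, R) {
  s <- 0
  for (j in 1:R) {
    for (k in j:(n - R + j)) {
      s <- s + (j / k) * choose(k - 1, j - 1) * choose(n - k, R - j) / choose(n, R)
    }
  }
  s / R
}

# A small hand-built series table covering the filter rules.
tiny_series <- function() {
  mk <- function(acc, title = "t", summary = "s", design = "d",
                 species = "Homo sapiens",
                 types = "expression profiling by array",
                 vendor = "Affymetrix", retired = FALSE, sub = FALSE,
                 labels = character(0)) {
    tibble::tibble(
      accession = acc, title = title, summary = summary,
      overall_design = design, species = species,
      experiment_types = list(types), platform_vendor = vendor,
      retired = retired, is_subseries = sub,
      condition_labels = list(labels)
    )
  }
  dplyr::bind_rows(
    mk("GSE1", vendor = "Agilent"),
    mk("GSE2", types = "expression profiling by high throughput sequencing",
       vendor = "Illumina"),
    mk("GSE3", types = "expression profiling by high throughput sequencing",
       vendor = "Affymetrix"),
    mk("GSE4", sub = TRUE),
    mk("GSE5", retired = TRUE),
    mk("GSE6", species = "Mus musculus"),
    mk("GSE7", vendor = "HomeBrew"),
    mk("GSE8", types = "methylation profiling by array")
  )
}

# JSON-lines text for a few series.
jsonl_lines <- function(objs) {
  vapply(objs, function(o) jsonlite::toJSON(o, auto_unbox = TRUE), character(1))
}
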