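make_corpus <- function(texts, policy = cleaning_policy(),
                        acc = sprintf("GSE%d", seq_along(texts))) {
  s <- tibble::tibble(
    accession = acc, title = texts, summary = "", overall_design = "",
    species = "Homo sapiens",
    experiment_types = rep(list("expression profiling by array"), length(texts)),
    platform_vendor = "Affymetrix", retired = FALSE, is_subseries = FALSE,
    condition_labels = rep(list(character(0)), length(texts))
  )
  clean_corpus(s, policy)
}

test_that("word overlap matches hand-worked values and is symmetric", {
  a <- c("parkinson", "disease", "brain", "cortex")
  b <- c("parkinson", "disease", "blood")
  expect_equal(word_overlap_similarity(a, b), 2 / 5)
  expect_equal(word_overlap_similarity(b, a), 2 / 5)
  expect_equal(word_overlap_similarity(a, a), 1)
  expect_equal(word_overlap_similarity(a, c("x", "y")), 0)
  expect_equal(word_overlap_similarity(character(0), character(0)), 0)
  # equals 1 iff unique-token sets are equal; repeated tokens don't matter
  expect_equal(word_overlap_similarity(c(a, a), a), 1)
  expect_lt(word_overlap_similarity(c(a, "extra"), a), 1)
})

test_that("bm25 index collects the documented statistics", {
  corp <- make_corpus(c("a", "a", "b"))
  idx <- bm25_index(corp)
  expect_equal(idx$doc_frequencies, c(a = 2L, b = 1L))
  expect_equal(idx$avg_doc_length, 1)
  expect_equal(unname(idx$doc_lengths), c(1L, 1L, 1L))
  single <- bm25_index(make_corpus("three word doc"))
  expect_equal(single$avg_doc_length, 3)
  expect_error(bm25_index(make_corpus("x"), mode = "plus"), "plus")
  expect_error(
    bm25_index(make_corpus("x", cleaning_policy(remove_stopwords = TRUE, stem = TRUE)),
               mode = "default"),
    "default"
  )
})

test_that("bm25 single-document score matches the closed form", {
  k1 <- 1.5; b <- 0.75
  corp <- make_corpus("term")
  idx <- bm25_index(corp, k1 = k1, b = b)
  # one doc, df = 1: idf = ln(1 + 0.5/1.5); tf = 1/(1 + k1*(1 - b + b*1/1))
  expect_equal(bm25_score(idx, "term", "GSE1"),
               log(1 + 0.5 / 1.5) * 1 / (1 + k1))
  expect_equal(bm25_score(idx, c("absent", "words"), "GSE1"), 0)
  expect_error(bm25_score(idx, "term", "GSE99"), "GSE99")
})

test_that("bm25 agrees with a straight-from-formula oracle on a toy corpus", {
  texts <- c(
    "parkinson brain cortex tissue sample",
    "parkinson blood serum sample",
    "breast tumor biopsy tissue tissue sample"
  )
  corp <- make_corpus(texts)
  idx <- bm25_index(corp, k1 = 1.2, b = 0.4)
  docs_tokens <- corp$tokens
  query <- c("parkinson", "tissue", "sample", "sample")
  for (i in seq_along(texts)) {
    expect_equal(
      bm25_score(idx, query, corp$accession[i]),
      bm25_bruteforce(docs_tokens, query, i, k1 = 1.2, b = 0.4),
      tolerance = 1e-12
    )
  }
})

test_that("bm25 is additive over query tokens and monotone in query size", {
  corp <- make_corpus(c("alpha beta gamma", "beta gamma delta", "delta epsilon"))
  idx <- bm25_index(corp)
  q <- c("beta", "delta", "epsilon")
  for (id in corp$accession) {
    parts <- vapply(q, function(t) bm25_score(idx, t, id), numeric(1))
    expect_equal(bm25_score(idx, q, id), sum(parts))
    expect_gte(bm25_score(idx, q, id), bm25_score(idx, q[-1], id))
  }
})

test_that("hashed tf-idf embedding is deterministic, normalised, and separates vocabularies", {
  corp <- make_corpus(c("one two three", "four five six"))
  st <- corpus_stats(corp)
  v1 <- hashed_tfidf_embed(corp$tokens[[1]], dim = 256, stats = st)
  v1b <- hashed_tfidf_embed(corp$tokens[[1]], dim = 256, stats = st)
  expect_identical(v1, v1b)
  expect_equal(sqrt(sum(v1^2)), 1)
  expect_equal(hashed_tfidf_embed(character(0), dim = 256, stats = st),
               numeric(256))
  v2 <- hashed_tfidf_embed(corp$tokens[[2]], dim = 256, stats = st)
  expect_lt(abs(cosine_similarity(v1, v2)), 0.2)
})

test_that("chunking reproduces the stated window arithmetic", {
  cfg <- chunking_config(enabled = TRUE)
  short <- strrep("x", 200)
  expect_equal(chunk_text(short, cfg), short)
  long <- strrep("abcde", 100) # 500 chars
  chunks <- chunk_text(long, cfg)
  expect_equal(nchar(chunks), c(256, 256, 28))
  expect_equal(chunks[1], substr(long, 1, 256))
  expect_equal(chunks[2], substr(long, 237, 492))
  expect_equal(chunks[3], substr(long, 473, 500))
  expect_equal(chunk_text("", cfg), "")
})

test_that("chunk round trip reconstructs the input", {
  cfg <- chunking_config(enabled = TRUE, threshold_chars = 64,
                         overlap_chars = 7, chunk_size_chars = 64)
  withr::with_seed(42, {
    for (i in 1:25) {
      n <- sample(0:400, 1)
      txt <- paste(sample(c(letters, " "), n, replace = TRUE), collapse = "")
      chunks <- chunk_text(txt, cfg)
      rebuilt <- paste0(chunks[1], paste(substring(chunks[-1], 8), collapse = ""))
      expect_identical(rebuilt, txt)
    }
  })
})

test_that("chunk-averaged embedding equals the mean of chunk vectors", {
  cfg <- chunking_config(enabled = TRUE, threshold_chars = 16,
                         overlap_chars = 0, chunk_size_chars = 16)
  corp <- make_corpus("aaaa bbbb cccc dddd eeee ffff")
  # toy backend: 2-d vector of (letter count, space count)
  fun <- function(txt) c(nchar(gsub(" ", "", txt)), nchar(gsub("[^ ]", "", txt)))
  mat <- embed_documents(corp, fun, cfg)
  chunks <- chunk_text(corp$text[1], cfg)
  expect_equal(mat[1, ], colMeans(do.call(rbind, lapply(chunks, fun))))
  # disabled config: backend applied to full text
  expect_equal(embed_documents(corp, fun, chunking_config())[1, ],
               fun(corp$text[1]))
  # mean of identical chunk vectors is that vector
  cfg2 <- chunking_config(enabled = TRUE, threshold_chars = 4,
                          overlap_chars = 0, chunk_size_chars = 4)
  corp2 <- make_corpus("abab abab abab")
  const_fun <- function(txt) c(1, 0)
  expect_equal(embed_documents(corp2, const_fun, cfg2)[1, ], c(1, 0))
})

test_that("vector tables round-trip and validate", {
  mat <- matrix(c(0.5, -1.25, 3, 2, 0, 1e-8), nrow = 2, byrow = TRUE,
                dimnames = list(c("GSE1", "GSE2"), NULL))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_vector_table(mat, path, backend_id = "toy")
  back <- read_vector_table(path)
  expect_equal(unname(back[, ]), unname(mat[, ]), tolerance = 1e-12)
  expect_equal(rownames(back), c("GSE1", "GSE2"))
  expect_equal(attr(back, "backend_id"), "external:toy")
  expect_error(
    read_vector_table(text = c("#backend_id=x\tdim=3", "GSE1\t1\t2")),
    "row 1"
  )
  expect_error(
    read_vector_table(text = c("#backend_id=x\tdim=2", "GSE1\t1\tb")),
    "row 1"
  )
})
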