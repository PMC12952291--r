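#' Known backend identifiers
#'
#' The backend registry keys similarity methods by string id:
#' `"word_overlap"` (Jaccard index of unique-token sets), `"bm25"` and
#' `"bm25plus"` (lucene-variant BM25, the plus mode on stemmed stop-word-free
#' tokens), `"hashed_tfidf"` (a deterministic signed-hash TF-IDF embedder
#' that stands in for neural sentence embedders so retrieval and evaluation
#' run offline), and `"external:<id>"` (precomputed vectors loaded with
#' [read_vector_table()]).
#'
#' @return Character vector of the built-in backend ids.
#' @export
backend_ids <- function() c("word_overlap", "bm25", "bm25plus", "hashed_tfidf")

backend_family <- function(backend_id) {
  if (startsWith(backend_id, "external:")) return("external")
  if (backend_id %in% backend_ids()) return(backend_id)
  abort(sprintf("unknown backend id '%s' (known: %s, external:<id>)",
                backend_id, paste(backend_ids(), collapse = ", ")))
}

#' Word-overlap (Jaccard) similarity
#'
#' The proportion of the unique words spanning two documents that occur in
#' both: `|A intersect B| / |A union B|` over unique-token sets, 0 when the
#' union is empty.
#'
#' @param a,b Character vectors of tokens (documents cleaned under the same
#'   policy), or single-row `clean_corpus` slices.
#' @return A number in `[0, 1]`.
#' @examples
#' word_overlap_similarity(c("parkinson", "disease", "brain", "cortex"),
#'                         c("parkinson", "disease", "blood"))
#' @export
word_overlap_similarity <- function(a, b) {
  a <- unique(as_tokens(a))
  b <- unique(as_tokens(b))
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

as_tokens <- function(x) {
  if (is.character(x)) return(x)
  if (inherits(x, "clean_corpus") || (is.data.frame(x) && "tokens" %in% names(x))) {
    if (nrow(x) != 1L) abort("expected a single document")
    return(x$tokens[[1]])
  }
  abort("cannot interpret input as a token vector")
}

#' Build a BM25 index over a cleaned corpus
#'
#' Collects the corpus statistics BM25 scoring needs: per-document term
#' frequencies and lengths, document frequencies, and the mean document
#' length. The `"plus"` mode requires the corpus policy to have
#' `remove_stopwords` and `stem` set; the `"default"` mode requires both
#' unset (mirroring the two ways the algorithm is applied in practice).
#'
#' @param corpus A [clean_corpus()].
#' @param k1 Term-frequency saturation parameter (default 1.5).
#' @param b Length-normalisation parameter in `[0, 1]` (default 0.75).
#' @param mode `"default"` or `"plus"`.
#' @return A `bm25_index` object.
#' @export
bm25_index <- function(corpus, k1 = 1.5, b = 0.75, mode = c("default", "plus")) {
  mode <- match.arg(mode)
  if (!is.data.frame(corpus) || nrow(corpus) == 0) abort("corpus must be a non-empty clean_corpus")
  stopifnot(k1 > 0, b >= 0, b <= 1)
  pol <- corpus_policy(corpus)
  if (mode == "plus" && !(pol$remove_stopwords && pol$stem)) {
    abort("bm25 mode 'plus' requires a policy with remove_stopwords and stem set")
  }
  if (mode == "default" && (pol$remove_stopwords || pol$stem)) {
    abort("bm25 mode 'default' requires a policy without remove_stopwords or stem")
  }
  tf <- lapply(corpus$tokens, function(t) {
    if (!length(t)) return(integer(0))
    tab <- table(t)
    stats::setNames(as.integer(tab), names(tab))
  })
  doc_lengths <- vapply(corpus$tokens, length, integer(1))
  df_tab <- table(unlist(lapply(tf, names), use.names = FALSE))
  doc_frequencies <- stats::setNames(as.integer(df_tab), names(df_tab))
  structure(list(
    doc_ids = corpus$accession,
    doc_lengths = stats::setNames(doc_lengths, corpus$accession),
    avg_doc_length = mean(doc_lengths),
    doc_frequencies = doc_frequencies,
    term_frequencies = stats::setNames(tf, corpus$accession),
    k1 = k1, b = b, mode = mode
  ), class = "bm25_index")
}

#' @export
print.bm25_index <- function(x, ...) {
  cat(sprintf("<bm25_index> %d docs, %d terms, avgdl %.2f, k1=%g b=%g mode=%s\n",
              length(x$doc_ids), length(x$doc_frequencies), x$avg_doc_length,
              x$k1, x$b, x$mode))
  invisible(x)
}

bm25_idf <- function(index, terms) {
  n <- length(index$doc_ids)
  df <- index$doc_frequencies[terms]
  df[is.na(df)] <- 0L
  log(1 + (n - df + 0.5) / (df + 0.5))
}

#' Score one document against a query with BM25
#'
#' The lucene variant: the score is the sum over query-token occurrences of
#' `IDF(t) * f(t,d) / (f(t,d) + k1 * (1 - b + b * |d| / avgdl))` with
#' `IDF(t) = ln(1 + (N - df(t) + 0.5) / (df(t) + 0.5))`. Tokens absent from
#' the indexed document contribute 0; repeated query tokens contribute once
#' per occurrence.
#'
#' @param index A [bm25_index()].
#' @param query_tokens Character vector of query tokens.
#' @param doc_id Accession of an indexed document.
#' @return Non-negative score.
#' @export
bm25_score <- function(index, query_tokens, doc_id) {
  if (!doc_id %in% index$doc_ids) abort(sprintf("doc_id '%s' not in index", doc_id))
  bm25_scores(index, query_tokens)[[doc_id]]
}

#' Score every indexed document against a query
#'
#' @inheritParams bm25_score
#' @return Named numeric vector of scores, one per indexed document, in index
#'   order.
#' @export
bm25_scores <- function(index, query_tokens) {
  qt <- table(query_tokens)
  terms <- names(qt)
  mult <- as.integer(qt)
  idf <- bm25_idf(index, terms)
  norm <- index$k1 * (1 - index$b + index$b * index$doc_lengths / index$avg_doc_length)
  scores <- stats::setNames(numeric(length(index$doc_ids)), index$doc_ids)
  for (id in index$doc_ids) {
    f <- index$term_frequencies[[id]][terms]
    f[is.na(f)] <- 0
    scores[[id]] <- sum(mult * idf * f / (f + norm[[id]]), na.rm = TRUE)
  }
  scores
}

#' Corpus statistics for TF-IDF weighting
#'
#' Document frequencies and corpus size over a cleaned corpus; the weighting
#' statistics for [hashed_tfidf_embed()] are computed on the candidate corpus
#' being searched.
#'
#' @param corpus A [clean_corpus()].
#' @return List with `doc_frequencies` (named integer) and `n_docs`.
#' @export
corpus_stats <- function(corpus) {
  df_tab <- table(unlist(lapply(corpus$tokens, unique), use.names = FALSE))
  list(
    doc_frequencies = stats::setNames(as.integer(df_tab), names(df_tab)),
    n_docs = nrow(corpus)
  )
}

# Signed hashing of a token: FNV-1a of the token picks the bucket, FNV-1a of
# the token with a salt suffix picks the sign. Fixed constants, no
# process-randomised hashing, so vectors are identical across runs/platforms.
token_bucket <- function(tokens, dim) fnv1a32(tokens) %% dim
token_sign <- function(tokens) ifelse(fnv1a32(paste0(tokens, "#s")) %% 2 == 0, 1, -1)

#' Deterministic hashed TF-IDF embedding
#'
#' Embeds a document into a fixed-length vector by hashing each token to a
#' signed bucket and accumulating `tf * ln((N + 1) / (df + 1))`; the result
#' is L2-normalised unless all-zero. This is the package's deterministic
#' vector backend: it exercises the same retrieval geometry (mean reference
#' vector, cosine ranking, chunk averaging) as neural sentence embedders
#' while remaining exactly reproducible offline.
#'
#' @param tokens Character vector of document tokens (or a 1-row
#'   `clean_corpus` slice).
#' @param dim Embedding dimension, at least 16 (default 256).
#' @param stats Corpus statistics from [corpus_stats()].
#' @return Numeric vector of length `dim`. An empty document yields the zero
#'   vector.
#' @export
hashed_tfidf_embed <- function(tokens, dim = 256, stats) {
  tokens <- as_tokens(tokens)
  stopifnot(dim >= 16)
  v <- numeric(dim)
  if (!length(tokens)) return(v)
  tf <- table(tokens)
  terms <- names(tf)
  df <- stats$doc_frequencies[terms]
  df[is.na(df)] <- 0L
  w <- as.integer(tf) * log((stats$n_docs + 1) / (df + 1))
  idx <- token_bucket(terms, dim) + 1
  sgn <- token_sign(terms)
  for (i in seq_along(terms)) v[idx[i]] <- v[idx[i]] + sgn[i] * w[i]
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  v
}

#' Chunking configuration
#'
#' Controls how long texts are split before embedding: texts at or below
#' `threshold_chars` stay whole; longer texts are cut into windows of
#' `chunk_size_chars` characters advancing by
#' `chunk_size_chars - overlap_chars`, the last window possibly shorter.
#' Boundaries are character-exact (they may split words).
#'
#' @param enabled Whether chunk-and-average aggregation is applied.
#' @param threshold_chars Length at or below which text is never split
#'   (default 256).
#' @param overlap_chars Overlap between consecutive chunks (default 20).
#' @param chunk_size_chars Window length (default 256).
#' @return A `chunking_config` object.
#' @export
chunking_config <- function(enabled = FALSE, threshold_chars = 256,
                            overlap_chars = 20, chunk_size_chars = 256) {
  stopifnot(threshold_chars > 0, chunk_size_chars > 0, overlap_chars >= 0)
  if (overlap_chars >= chunk_size_chars) {
    abort("overlap_chars must be smaller than chunk_size_chars")
  }
  if (enabled && threshold_chars < chunk_size_chars) {
    abort("threshold_chars must be at least chunk_size_chars when chunking is enabled")
  }
  structure(list(enabled = enabled, threshold_chars = threshold_chars,
                 overlap_chars = overlap_chars,
                 chunk_size_chars = chunk_size_chars),
            class = "chunking_config")
}

#' Split text into overlapping character chunks
#'
#' @param text A single string.
#' @param config A [chunking_config()] with `enabled = TRUE`.
#' @return Character vector of chunks. Dropping the first `overlap_chars`
#'   characters of every chunk after the first and concatenating reproduces
#'   `text` exactly.
#' @export
chunk_text <- function(text, config) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!isTRUE(config$enabled)) abort("chunk_text requires an enabled chunking_config")
  n <- nchar(text)
  if (n <= config$threshold_chars) return(text)
  stride <- config$chunk_size_chars - config$overlap_chars
  starts <- 1
  while (starts[length(starts)] + config$chunk_size_chars - 1 < n) {
    starts <- c(starts, starts[length(starts)] + stride)
  }
  vapply(starts, function(s) substr(text, s, min(s + config$chunk_size_chars - 1, n)),
         character(1))
}

#' Embed documents, optionally chunk-averaged
#'
#' Applies a per-text embedding function to each document of a cleaned
#' corpus. With chunking disabled the backend sees the full text; enabled,
#' each text is split with [chunk_text()], each chunk embedded, and the
#' unweighted arithmetic mean of the chunk vectors returned.
#'
#' @param corpus A [clean_corpus()].
#' @param embed_fun Function taking one string and returning a numeric vector
#'   of fixed length.
#' @param config A [chunking_config()].
#' @return Numeric matrix, one row per document, rownames = accessions.
#' @export
embed_documents <- function(corpus, embed_fun, config = chunking_config()) {
  vecs <- lapply(seq_len(nrow(corpus)), function(i) {
    txt <- corpus$text[i]
    if (!isTRUE(config$enabled) || nchar(txt) <= config$threshold_chars) {
      embed_fun(txt)
    } else {
      chunks <- chunk_text(txt, config)
      mats <- lapply(chunks, embed_fun)
      dims <- vapply(mats, length, integer(1))
      if (length(unique(dims)) != 1L) abort("backend returned inconsistent embedding dims")
      colMeans(do.call(rbind, mats))
    }
  })
  dims <- vapply(vecs, length, integer(1))
  if (length(unique(dims)) != 1L) abort("backend returned inconsistent embedding dims")
  mat <- do.call(rbind, vecs)
  rownames(mat) <- corpus$accession
  mat
}

#' Read precomputed embedding vectors
#'
#' Reads the adapter format for externally computed embeddings (e.g. from a
#' neural sentence-embedding model): a TSV whose first line is
#' `#backend_id=<id>\tdim=<d>` and whose rows are an accession followed by
#' `d` numeric fields.
#'
#' @param path File path (or `text`, a character vector of lines).
#' @param text Optional character vector of lines.
#' @return Numeric matrix with rownames = accessions and attribute
#'   `backend_id`.
#' @export
read_vector_table <- function(path = NULL, text = NULL) {
  lines <- text %||% readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "#")) {
    abort("vector table must start with a '#backend_id=<id>\tdim=<d>' header")
  }
  hdr <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  kv <- strsplit(hdr, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  backend_id <- vals[match("backend_id", keys)]
  dim <- suppressWarnings(as.integer(vals[match("dim", keys)]))
  if (is.na(backend_id) || is.na(dim) || dim < 1) abort("invalid vector-table header")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  rows <- strsplit(body, "\t", fixed = TRUE)
  mat <- matrix(NA_real_, nrow = length(rows), ncol = dim)
  acc <- character(length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != dim + 1L) {
      abort(sprintf("row %d has %d fields, expected %d", i, length(r), dim + 1L))
    }
    acc[i] <- r[1]
    vals_i <- suppressWarnings(as.numeric(r[-1]))
    if (anyNA(vals_i)) abort(sprintf("row %d contains non-numeric values", i))
    mat[i, ] <- vals_i
  }
  rownames(mat) <- acc
  attr(mat, "backend_id") <- paste0("external:", backend_id)
  mat
}

#' Write an embedding matrix as a vector table
#'
#' @param mat Numeric matrix with accession rownames.
#' @param path Output path.
#' @param backend_id Backend identifier for the header (without the
#'   `external:` prefix).
#' @return `path`, invisibly.
#' @export
write_vector_table <- function(mat, path, backend_id = "custom") {
  hdr <- sprintf("#backend_id=%s\tdim=%d", backend_id, ncol(mat))
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], format(mat[i, ], digits = 17, trim = TRUE,
                                     scientific = FALSE)), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path, useBytes = TRUE)
  invisible(path)
}
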