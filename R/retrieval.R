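#' Cosine similarity
#'
#' `dot(u, v) / (||u|| ||v||)`; defined as 0 when either vector has zero
#' norm, so empty documents rank last rather than erroring.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A number in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) abort("cosine_similarity: dimension mismatch")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

#' Mean of a set of embedding vectors
#'
#' The element-wise unweighted arithmetic mean — the representation of a
#' reference set of known-relevant series.
#'
#' @param mat Numeric matrix, one embedding per row (as returned by
#'   [embed_documents()] or [read_vector_table()]), or a list of equal-length
#'   numeric vectors.
#' @return Numeric vector of column means.
#' @export
mean_embedding <- function(mat) {
  if (is.list(mat) && !is.data.frame(mat)) {
    dims <- vapply(mat, length, integer(1))
    if (!length(mat)) abort("mean_embedding: empty input")
    if (length(unique(dims)) != 1L) abort("mean_embedding: mixed dimensions")
    mat <- do.call(rbind, mat)
  }
  if (!is.matrix(mat) || nrow(mat) == 0) abort("mean_embedding: empty input")
  colMeans(mat)
}

#' Rank candidate series against a reference set
#'
#' The core retrieval flow: the user supplies a reference set of
#' known-relevant series; every other series in the corpus is scored against
#' it and returned in ranked order. Vector backends (`hashed_tfidf`,
#' `external:<id>`) average the reference embeddings and rank candidates by
#' cosine similarity to that mean. `word_overlap` scores each candidate
#' against the pooled unique-token set of the reference documents. `bm25` /
#' `bm25plus` build an index over the candidates and use the concatenated
#' reference tokens as the query. Ties are broken by ascending accession, so
#' the ranking is deterministic and invariant to candidate input order.
#'
#' @param series A series tibble (see [read_series()]) containing reference
#'   and candidate series.
#' @param reference Character vector of reference accessions (all present in
#'   `series`); reference series are excluded from the candidates.
#' @param backend_id Backend identifier (see [backend_ids()]).
#' @param policy Cleaning policy; defaults to [default_policy()] for the
#'   backend.
#' @param config A [chunking_config()]; affects vector backends only.
#' @param condition Optional condition name; when given, each candidate's
#'   `relevant` flag is whether its `condition_labels` contain it, otherwise
#'   `relevant` is `NA`.
#' @param vectors For `external:<id>` backends, the matrix from
#'   [read_vector_table()] covering reference and candidate accessions.
#' @param dim Embedding dimension for the `hashed_tfidf` backend.
#' @return A `geo_ranking`: tibble with columns `rank`, `accession`, `score`,
#'   `relevant`, `flagged` (TRUE for candidates whose cleaned text was
#'   empty), sorted by descending score then ascending accession, with
#'   attributes `condition`, `backend_id`, `policy`, `chunking`.
#' @export
rank_by_reference <- function(series, reference, backend_id,
                              policy = NULL, config = chunking_config(),
                              condition = NULL, vectors = NULL, dim = 256) {
  check_series(series)
  family <- backend_family(backend_id)
  policy <- policy %||% default_policy(backend_id)
  if (!length(reference)) abort("reference set is empty")
  missing <- setdiff(reference, series$accession)
  if (length(missing)) {
    abort(sprintf("reference accession(s) not in corpus: %s",
                  paste(missing, collapse = ", ")))
  }
  is_ref <- series$accession %in% reference
  cand <- series[!is_ref, , drop = FALSE]
  refs <- series[is_ref, , drop = FALSE]
  if (!nrow(cand)) abort("no candidate series remain after removing the reference set")

  cand_corpus <- clean_corpus(cand, policy)
  ref_corpus <- clean_corpus(refs, policy)
  flagged <- !nzchar(cand_corpus$text)

  score <- switch(family,
    word_overlap = {
      pool <- unique(unlist(ref_corpus$tokens, use.names = FALSE))
      vapply(cand_corpus$tokens, function(t) {
        if (!length(t)) return(0)
        word_overlap_similarity(t, pool)
      }, numeric(1))
    },
    bm25 = ,
    bm25plus = {
      idx <- bm25_index(cand_corpus, mode = if (family == "bm25plus") "plus" else "default")
      query <- unlist(ref_corpus$tokens, use.names = FALSE)
      unname(bm25_scores(idx, query))
    },
    hashed_tfidf = {
      stats <- corpus_stats(cand_corpus)
      embed <- function(txt) {
        hashed_tfidf_embed(tokenize(txt)[[1]], dim = dim, stats = stats)
      }
      cand_mat <- embed_documents(cand_corpus, embed, config)
      ref_mat <- embed_documents(ref_corpus, embed, config)
      centroid <- mean_embedding(ref_mat)
      apply(cand_mat, 1, cosine_similarity, v = centroid)
    },
    external = {
      if (is.null(vectors)) abort("external backend requires a 'vectors' matrix")
      need <- c(refs$accession, cand$accession)
      absent <- setdiff(need, rownames(vectors))
      if (length(absent)) {
        abort(sprintf("vectors missing for accession(s): %s",
                      paste(absent, collapse = ", ")))
      }
      centroid <- mean_embedding(vectors[refs$accession, , drop = FALSE])
      apply(vectors[cand$accession, , drop = FALSE], 1, cosine_similarity,
            v = centroid)
    }
  )
  score[flagged] <- 0

  relevant <- if (is.null(condition)) {
    rep(NA, nrow(cand))
  } else {
    vapply(cand$condition_labels, function(l) condition %in% l, logical(1))
  }

  out <- tibble(
    accession = cand$accession,
    score = as.numeric(score),
    relevant = relevant,
    flagged = flagged
  )
  out <- dplyr::arrange(out, dplyr::desc(score), accession)
  out <- dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
  structure(out,
            condition = condition, backend_id = backend_id,
            policy = policy, chunking = config,
            class = c("geo_ranking", class(out)))
}

#' Write a ranking as TSV with a JSON sidecar
#'
#' The TSV has columns `rank`, `accession`, `score`, `relevant`; the sidecar
#' (`<path>.meta.json`) records the condition, backend id, and chunking
#' configuration.
#'
#' @param ranking A `geo_ranking` from [rank_by_reference()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  readr::write_tsv(ranking[, c("rank", "accession", "score", "relevant")], path)
  cfg <- attr(ranking, "chunking")
  meta <- list(
    condition = attr(ranking, "condition"),
    backend_id = attr(ranking, "backend_id"),
    chunking = unclass(cfg),
    policy = unclass(attr(ranking, "policy"))
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a reference accession list
#'
#' Accepts either one accession per line or the tab-delimited export dialect
#' with an `Accession` column.
#'
#' @param path File path.
#' @return Character vector of accessions.
#' @export
read_accession_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(sprintf("no accessions found in '%s'", path))
  if (grepl("\t", lines[1])) {
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    col <- match("Accession", header)
    if (is.na(col)) abort("tab-delimited accession file lacks an 'Accession' column")
    vapply(strsplit(lines[-1], "\t", fixed = TRUE), `[`, character(1), col)
  } else {
    trimws(lines)
  }
}
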