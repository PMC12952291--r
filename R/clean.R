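#' Text-cleaning policy
#'
#' A cleaning policy records which normalisation steps are applied to the
#' composed free-text description of a series before it is represented.
#' The steps run in a fixed order: strip HTML tags, strip URLs, lower-case,
#' replace non-alphanumeric characters with spaces, collapse whitespace,
#' tokenise on single spaces, remove stop words, stem. Every cleaned corpus
#' carries its policy so downstream backends can verify their contract
#' (e.g. `bm25plus` requires stop-word removal and stemming).
#'
#' @param lowercase Convert text to lower case.
#' @param strip_html Remove HTML tags (`<...>`).
#' @param strip_urls Remove scheme-prefixed (`http://`, `https://`, `ftp://`)
#'   and `www.`-prefixed substrings up to the next whitespace.
#' @param strip_non_alphanumeric Replace every non-alphanumeric character with
#'   a space, so tokens joined by punctuation (`"TNBC/ER-"`) split apart
#'   rather than fusing.
#' @param collapse_whitespace Collapse whitespace runs to single spaces and
#'   trim the ends.
#' @param remove_stopwords Drop tokens found in the bundled English stop-word
#'   list (see [geo_stopwords()]).
#' @param stem Apply the Porter stemmer to each surviving token.
#' @return An object of class `cleaning_policy` (a named list of the seven
#'   logical flags).
#' @seealso [clean_text()], [clean_corpus()], [default_policy()]
#' @export
cleaning_policy <- function(lowercase = TRUE, strip_html = TRUE,
                            strip_urls = TRUE, strip_non_alphanumeric = TRUE,
                            collapse_whitespace = TRUE,
                            remove_stopwords = FALSE, stem = FALSE) {
  pol <- list(
    lowercase = lowercase, strip_html = strip_html, strip_urls = strip_urls,
    strip_non_alphanumeric = strip_non_alphanumeric,
    collapse_whitespace = collapse_whitespace,
    remove_stopwords = remove_stopwords, stem = stem
  )
  for (nm in names(pol)) {
    if (!is.logical(pol[[nm]]) || length(pol[[nm]]) != 1L || is.na(pol[[nm]])) {
      abort(sprintf("cleaning_policy flag '%s' must be TRUE or FALSE", nm))
    }
  }
  structure(pol, class = "cleaning_policy")
}

#' @export
print.cleaning_policy <- function(x, ...) {
  on <- names(x)[vapply(x, isTRUE, logical(1))]
  cat("<cleaning_policy> ", paste(on, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Default cleaning policy for a backend
#'
#' Frequency-based backends (`word_overlap`, `bm25plus`, `hashed_tfidf`) do not
#' benefit from function words, so their default policies remove stop words;
#' `bm25plus` additionally stems. `bm25` (the plain mode) and external
#' embedding backends keep stop words because contextual models use them.
#'
#' @param backend_id One of `"word_overlap"`, `"bm25"`, `"bm25plus"`,
#'   `"hashed_tfidf"`, or `"external:<id>"`.
#' @return A [cleaning_policy()].
#' @export
default_policy <- function(backend_id) {
  base <- cleaning_policy()
  switch(backend_family(backend_id),
    word_overlap = cleaning_policy(remove_stopwords = TRUE),
    bm25 = base,
    bm25plus = cleaning_policy(remove_stopwords = TRUE, stem = TRUE),
    hashed_tfidf = cleaning_policy(remove_stopwords = TRUE),
    external = base
  )
}

#' Bundled English stop-word list
#'
#' Reads the stop-word file shipped with the package (one token per line).
#' Because stop-word removal runs after punctuation stripping, the effective
#' stop set also includes the cleaned fragments of contractions
#' (e.g. `"aren't"` contributes `"aren"` and `"t"`).
#'
#' @return Character vector of stop tokens.
#' @export
geo_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "geosift")
  raw <- readLines(path, encoding = "UTF-8")
  frag <- unlist(strsplit(gsub("[^a-z0-9]", " ", tolower(raw)), " +"))
  unique(frag[nzchar(frag)])
}

#' Clean free text under a policy
#'
#' Applies the policy's steps in their fixed order and returns the cleaned
#' text (the space-join of the surviving tokens). Vectorised over `x`.
#'
#' @param x Character vector of raw texts.
#' @param policy A [cleaning_policy()].
#' @return Character vector of cleaned texts. Cleaning may yield `""`;
#'   downstream ranking flags such documents rather than erroring.
#' @examples
#' clean_text("Breast <b>Cancer</b>! see https://x.org", cleaning_policy())
#' @export
clean_text <- function(x, policy = cleaning_policy()) {
  stopifnot(inherits(policy, "cleaning_policy"), is.character(x))
  if (policy$strip_html) x <- gsub("<[^>]*>", " ", x)
  if (policy$strip_urls) {
    x <- gsub("(?i)(https?://|ftp://|www\\.)[^[:space:]]*", " ", x, perl = TRUE)
  }
  if (policy$lowercase) x <- tolower(x)
  if (policy$strip_non_alphanumeric) x <- gsub("[^a-zA-Z0-9]", " ", x)
  if (policy$collapse_whitespace) {
    x <- gsub("[[:space:]]+", " ", x)
    x <- trimws(x)
  }
  toks <- tokenize(x)
  if (policy$remove_stopwords) {
    sw <- geo_stopwords()
    toks <- lapply(toks, function(t) t[!(t %in% sw)])
  }
  if (policy$stem) toks <- lapply(toks, porter_stem)
  vapply(toks, paste, character(1), collapse = " ")
}

# Whitespace tokenizer; "" yields character(0).
tokenize <- function(x) {
  lapply(strsplit(x, " ", fixed = TRUE), function(t) t[nzchar(t)])
}

#' Compose the searchable document for each series
#'
#' Concatenates `title`, `summary`, and `overall_design` in that order,
#' separated by single spaces, skipping empty fields — the same three
#' free-text fields a GEO submitter provides.
#'
#' @param series A series tibble (see [read_series()]).
#' @return Tibble with columns `accession`, `text`.
#' @export
compose_documents <- function(series) {
  check_series(series)
  parts <- Map(function(t, s, d) {
    p <- c(t, s, d)
    p <- p[!is.na(p) & nzchar(trimws(p))]
    paste(p, collapse = " ")
  }, series$title, series$summary, series$overall_design)
  text <- unlist(parts, use.names = FALSE)
  empty <- !nzchar(text)
  if (any(empty)) {
    abort(sprintf(
      "series with no text in title, summary, or overall_design: %s",
      paste(series$accession[empty], collapse = ", ")
    ))
  }
  tibble(accession = series$accession, text = text)
}

#' Clean a series corpus into documents
#'
#' Composes each series' text fields and cleans them under one policy,
#' producing the document table every representation backend consumes.
#'
#' @param series A series tibble (see [read_series()]).
#' @param policy A [cleaning_policy()].
#' @return A `clean_corpus`: tibble with columns `accession`, `text` (cleaned),
#'   `tokens` (list column), `char_length` (`nchar(text)`), carrying the
#'   policy in its `"policy"` attribute.
#' @export
clean_corpus <- function(series, policy = cleaning_policy()) {
  docs <- compose_documents(series)
  cleaned <- clean_text(docs$text, policy)
  out <- tibble(
    accession = docs$accession,
    text = cleaned,
    tokens = tokenize(cleaned),
    char_length = nchar(cleaned)
  )
  structure(out, policy = policy, class = c("clean_corpus", class(out)))
}

corpus_policy <- function(corpus) {
  pol <- attr(corpus, "policy")
  if (is.null(pol)) abort("corpus has no cleaning-policy attribute; build it with clean_corpus()")
  pol
}
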