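#' Configuration for the synthetic labelled corpus generator
#'
#' The generator emulates the structure that makes series retrieval by text
#' similarity possible: each condition has a distinctive vocabulary that its
#' series' free-text descriptions draw on, mixed with shared background
#' vocabulary, plus distractor series written entirely in background
#' language. Tokens are pronounceable pseudo-words from a seeded generator,
#' so the text superficially resembles prose without copying any real
#' vocabulary.
#'
#' @param n_conditions Number of conditions (default 6, matching a
#'   six-condition study design).
#' @param series_per_condition Annotated series per condition (default 12,
#'   the smallest condition size the design targets). Override per condition
#'   with `per_condition_sizes` to mirror asymmetric condition sizes.
#' @param n_distractors Unannotated background-only series (default 100).
#' @param condition_vocab_size Tokens in each condition's vocabulary
#'   (default 25).
#' @param shared_vocab_size Background vocabulary size (default 200).
#' @param cross_condition_overlap Fraction in `[0, 1]` of each condition's
#'   vocabulary drawn from a confusable pool shared across conditions, so
#'   higher values make conditions harder to tell apart (default 0).
#' @param condition_token_rate Probability in `(0, 1]` that a token of an
#'   annotated series comes from its condition vocabulary rather than the
#'   background (default 0.8).
#' @param doc_length_range Integer `(min, max)` token count per document
#'   (default `c(40, 120)`).
#' @param seed Integer seed; the corpus is deterministic given the config.
#' @param per_condition_sizes Optional integer vector of length
#'   `n_conditions` overriding `series_per_condition`.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_conditions = 6, series_per_condition = 12,
                             n_distractors = 100, condition_vocab_size = 25,
                             shared_vocab_size = 200,
                             cross_condition_overlap = 0,
                             condition_token_rate = 0.8,
                             doc_length_range = c(40, 120), seed = 1,
                             per_condition_sizes = NULL) {
  stopifnot(
    n_conditions >= 1, series_per_condition >= 1, n_distractors >= 0,
    condition_vocab_size >= 1, shared_vocab_size >= 0,
    cross_condition_overlap >= 0, cross_condition_overlap <= 1,
    condition_token_rate > 0, condition_token_rate <= 1,
    length(doc_length_range) == 2, doc_length_range[1] >= 1,
    doc_length_range[2] >= doc_length_range[1]
  )
  sizes <- per_condition_sizes %||% rep(series_per_condition, n_conditions)
  if (length(sizes) != n_conditions || any(sizes < 1)) {
    abort("per_condition_sizes must give a positive count for each condition")
  }
  if (cross_condition_overlap > 0 && n_conditions < 2) {
    abort("cross_condition_overlap > 0 requires at least 2 conditions")
  }
  if (condition_token_rate < 1 && shared_vocab_size == 0) {
    abort("condition_token_rate < 1 requires a non-empty shared vocabulary")
  }
  structure(list(
    n_conditions = n_conditions, per_condition_sizes = as.integer(sizes),
    n_distractors = n_distractors,
    condition_vocab_size = condition_vocab_size,
    shared_vocab_size = shared_vocab_size,
    cross_condition_overlap = cross_condition_overlap,
    condition_token_rate = condition_token_rate,
    doc_length_range = as.integer(doc_length_range), seed = seed
  ), class = "synthetic_config")
}

# Pronounceable pseudo-words: 3 consonant-vowel syllables, e.g. "bakuro".
# Drawn without replacement from the shuffled syllable-product space and
# filtered against the stop-word list so cleaning never deletes them. The
# vowel set excludes 'e' and the consonant set excludes 'w', 'x', 'y', so no
# Porter suffix rule can fire on these words: stemming is the identity on
# them and condition vocabularies stay disjoint under every policy.
pseudo_words <- function(n) {
  consonants <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vowels <- c("a", "i", "o", "u")
  syl <- as.vector(outer(consonants, vowels, paste0))
  words <- as.vector(outer(as.vector(outer(syl, syl, paste0)), syl, paste0))
  words <- setdiff(words, geo_stopwords())
  if (n > length(words)) abort("requested more pseudo-words than the generator space holds")
  sample(words, n)
}

#' Generate a synthetic GEO-like labelled corpus
#'
#' Builds one series record per annotated series and distractor. Each
#' condition receives a vocabulary of `condition_vocab_size` pseudo-words, of
#' which a `cross_condition_overlap` fraction is drawn from a confusable pool
#' shared across all conditions (making conditions increasingly
#' indistinguishable as the overlap rises). Each annotated document is a
#' random token mixture — condition tokens with probability
#' `condition_token_rate`, background tokens otherwise — of length uniform in
#' `doc_length_range`, partitioned into title (10%), summary (60%), and
#' overall design (30%). Distractors draw only background tokens. Fixed
#' filler values (Homo sapiens, array profiling on Affymetrix) make every
#' record pass [filter_series()].
#'
#' @param config A [synthetic_config()].
#' @return A series tibble (see [read_series()]) with `condition_labels` set
#'   for annotated series and empty for distractors; deterministic given the
#'   config seed.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  nc <- config$n_conditions
  v <- config$condition_vocab_size
  n_overlap <- round(config$cross_condition_overlap * v)
  pool_size <- if (n_overlap > 0) v else 0
  words <- pseudo_words(nc * v + config$shared_vocab_size + pool_size)
  background <- words[seq_len(config$shared_vocab_size)]
  rest <- words[-seq_len(max(config$shared_vocab_size, 0))]
  confusable <- if (pool_size > 0) rest[seq_len(pool_size)] else character(0)
  own <- matrix(rest[pool_size + seq_len(nc * v)], nrow = nc, byrow = TRUE)
  vocab <- lapply(seq_len(nc), function(i) {
    kept <- own[i, seq_len(v - n_overlap)]
    borrowed <- if (n_overlap > 0) sample(confusable, n_overlap) else character(0)
    c(kept, borrowed)
  })
  cond_names <- sprintf("condition_%02d", seq_len(nc))

  make_doc <- function(cond_vocab) {
    rng <- config$doc_length_range
    len <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1) - 1L
    from_cond <- stats::runif(len) <= config$condition_token_rate
    toks <- character(len)
    if (is.null(cond_vocab)) from_cond[] <- FALSE
    if (any(from_cond)) toks[from_cond] <- sample(cond_vocab, sum(from_cond), replace = TRUE)
    if (any(!from_cond)) toks[!from_cond] <- sample(background, sum(!from_cond), replace = TRUE)
    n_title <- max(3L, round(0.1 * len))
    n_summary <- round(0.6 * len)
    list(
      title = paste(toks[seq_len(min(n_title, len))], collapse = " "),
      summary = paste(toks[seq_len(len) > n_title &
                             seq_len(len) <= n_title + n_summary], collapse = " "),
      overall_design = paste(toks[seq_len(len) > n_title + n_summary], collapse = " ")
    )
  }

  rows <- list()
  i_acc <- 0L
  for (ci in seq_len(nc)) {
    for (s in seq_len(config$per_condition_sizes[ci])) {
      i_acc <- i_acc + 1L
      doc <- make_doc(vocab[[ci]])
      rows[[i_acc]] <- c(doc, list(labels = cond_names[ci]))
    }
  }
  for (d in seq_len(config$n_distractors)) {
    i_acc <- i_acc + 1L
    doc <- make_doc(NULL)
    rows[[i_acc]] <- c(doc, list(labels = character(0)))
  }

  tibble(
    accession = sprintf("GSE%05d", seq_along(rows)),
    title = vapply(rows, `[[`, character(1), "title"),
    summary = vapply(rows, `[[`, character(1), "summary"),
    overall_design = vapply(rows, `[[`, character(1), "overall_design"),
    species = "Homo sapiens",
    experiment_types = rep(list("expression profiling by array"), length(rows)),
    platform_vendor = "Affymetrix",
    retired = FALSE,
    is_subseries = FALSE,
    condition_labels = lapply(rows, `[[`, "labels")
  )
}

#' Inject removable noise into a corpus
#'
#' Degrades the free-text fields with HTML tags, URLs, random casing, and
#' punctuation at the given per-token rates, leaving label structure
#' unchanged. All injected material is removable by [clean_text()] under the
#' default policy, so cleaning the degraded corpus restores the pristine
#' token multisets — which is what makes the cleaning pipeline testable
#' end-to-end.
#'
#' @param series A series tibble.
#' @param html_noise,url_noise,casing_noise,punct_noise Per-token injection
#'   rates in `[0, 1]`.
#' @param seed Integer seed.
#' @return The degraded series tibble (identical when all rates are 0).
#' @export
degrade_corpus <- function(series, html_noise = 0, url_noise = 0,
                           casing_noise = 0, punct_noise = 0, seed = 1) {
  check_series(series)
  rates <- c(html_noise, url_noise, casing_noise, punct_noise)
  stopifnot(all(rates >= 0), all(rates <= 1))
  if (all(rates == 0)) return(series)
  withr::with_seed(seed, {
    for (col in c("title", "summary", "overall_design")) {
      series[[col]] <- vapply(series[[col]], function(txt) {
        toks <- strsplit(txt, " ", fixed = TRUE)[[1]]
        toks <- toks[nzchar(toks)]
        if (!length(toks)) return(txt)
        out <- vapply(toks, function(tok) {
          if (stats::runif(1) <= casing_noise) {
            ch <- strsplit(tok, "")[[1]]
            up <- stats::runif(length(ch)) < 0.5
            tok <- paste(ifelse(up, toupper(ch), ch), collapse = "")
          }
          if (stats::runif(1) <= punct_noise) {
            tok <- paste0(tok, sample(c(",", ".", ";", ":", "!", ")"), 1))
          }
          if (stats::runif(1) <= html_noise) {
            tok <- paste0("<b>", tok, "</b>")
          }
          if (stats::runif(1) <= url_noise) {
            tok <- paste(tok, paste0("https://example.org/", sample(letters, 1)))
          }
          tok
        }, character(1), USE.NAMES = FALSE)
        paste(out, collapse = " ")
      }, character(1), USE.NAMES = FALSE)
    }
    series
  })
}
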