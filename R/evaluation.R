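#' Split a condition's annotated series into reference and comparison sets
#'
#' Uniformly permutes the condition's annotated accessions under `seed` and
#' assigns the first half to the reference set and the rest to comparison set
#' A; with an odd count the reference set receives the extra member.
#' Comparison set B is everything else in the annotated pool — series
#' annotated for other conditions or for none.
#'
#' @param annotated Accessions annotated for the condition (at least 2).
#' @param all_annotated The full pool of candidate accessions
#'   (`annotated` must be a subset).
#' @param condition Condition name.
#' @param seed Integer seed; the same seed reproduces the same plan.
#' @return A `split_plan`: list with `condition`, `reference`,
#'   `comparison_a`, `comparison_b`, `seed`.
#' @export
make_split <- function(annotated, all_annotated, condition, seed) {
  if (length(annotated) < 2) {
    abort(sprintf("condition '%s' has %d annotated series; at least 2 required",
                  condition, length(annotated)))
  }
  if (length(setdiff(annotated, all_annotated))) {
    abort("annotated accessions must be a subset of the full pool")
  }
  perm <- withr::with_seed(seed, sample(annotated))
  k <- ceiling(length(perm) / 2)
  structure(list(
    condition = condition,
    reference = perm[seq_len(k)],
    comparison_a = perm[-seq_len(k)],
    comparison_b = setdiff(all_annotated, annotated),
    seed = seed
  ), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> '%s': %d reference, %d comparison A, %d comparison B (seed %s)\n",
              x$condition, length(x$reference), length(x$comparison_a),
              length(x$comparison_b), format(x$seed)))
  invisible(x)
}

#' Subsample the irrelevant pool to a target imbalance ratio
#'
#' An imbalance ratio of `r` means the irrelevant pool contains `r` times as
#' many series as comparison set A; `"all"` keeps the full pool.
#'
#' @param comparison_b Accessions of the irrelevant pool.
#' @param comparison_a_size Number of relevant comparison series.
#' @param ratio Positive integer or `"all"`.
#' @param seed Integer seed for the uniform sample without replacement.
#' @return Character vector of sampled accessions.
#' @export
subsample_imbalance <- function(comparison_b, comparison_a_size, ratio, seed) {
  if (identical(ratio, "all")) return(comparison_b)
  ratio <- as.integer(ratio)
  stopifnot(ratio >= 1, comparison_a_size >= 1)
  need <- ratio * comparison_a_size
  if (need > length(comparison_b)) {
    abort(sprintf("requested %d irrelevant series but pool has only %d",
                  need, length(comparison_b)))
  }
  withr::with_seed(seed, sample(comparison_b, need))
}

#' Area under the precision-recall curve (average precision)
#'
#' Computed as average precision: the mean over relevant entries, at their
#' ranks `k`, of precision at `k` — the ranking-native estimator, with no
#' trapezoidal interpolation. Ties have already been resolved by the
#' ranking's deterministic ordering contract.
#'
#' @param result A `geo_ranking` with known `relevant` labels, or a logical
#'   vector of relevance labels in rank order.
#' @return AUPRC in `[0, 1]`.
#' @export
precision_recall_auc <- function(result) {
  l <- relevance_labels(result)
  if (anyNA(l)) abort("relevance labels must be known to compute AUPRC")
  if (!any(l)) abort("no relevant entries in ranking")
  if (all(l)) abort("no irrelevant entries in ranking")
  prec <- cumsum(l) / seq_along(l)
  sum(prec[l]) / sum(l)
}

relevance_labels <- function(result) {
  if (is.logical(result)) return(result)
  if (is.numeric(result)) return(result != 0)
  if (is.data.frame(result) && "relevant" %in% names(result)) {
    return(as.logical(result$relevant))
  }
  abort("cannot interpret input as relevance labels")
}

#' Recall at n
#'
#' The fraction of all relevant entries appearing among the top `n` ranked
#' results; `n` beyond the list length gives full-list recall.
#'
#' @param result A `geo_ranking` with known labels, or a logical label
#'   vector in rank order.
#' @param n Positive integer cutoff(s); vectorised.
#' @return Numeric vector of recalls in `[0, 1]`.
#' @export
recall_at_n <- function(result, n) {
  l <- relevance_labels(result)
  if (anyNA(l)) abort("relevance labels must be known to compute recall")
  total <- sum(l)
  vapply(n, function(k) {
    if (k <= 0) return(0)
    k <- min(k, length(l))
    if (total == 0) return(0)
    sum(l[seq_len(k)]) / total
  }, numeric(1))
}

#' Median model rank across conditions
#'
#' Within each condition, backends are ranked by descending AUPRC (ties get
#' the average rank); the output is each backend's median rank across
#' conditions — the aggregation used to compare many models when raw AUPRCs
#' are not comparable across conditions.
#'
#' @param results Tibble with columns `condition`, `backend_id`, `auprc`
#'   (one row per pair; every backend scored on every condition).
#' @return Tibble with columns `backend_id`, `median_rank`, sorted by
#'   `median_rank`.
#' @export
median_rank_table <- function(results) {
  stopifnot(all(c("condition", "backend_id", "auprc") %in% names(results)))
  grid <- tidyr::expand_grid(
    condition = unique(results$condition),
    backend_id = unique(results$backend_id)
  )
  have <- dplyr::distinct(results[, c("condition", "backend_id")])
  gaps <- dplyr::anti_join(grid, have, by = c("condition", "backend_id"))
  if (nrow(gaps)) {
    abort(sprintf("missing AUPRC cell(s): %s",
                  paste(paste(gaps$condition, gaps$backend_id, sep = "/"),
                        collapse = ", ")))
  }
  results |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(model_rank = rank(-.data$auprc, ties.method = "average")) |>
    dplyr::group_by(.data$backend_id) |>
    dplyr::summarise(median_rank = stats::median(.data$model_rank),
                     .groups = "drop") |>
    dplyr::arrange(.data$median_rank, .data$backend_id)
}

#' Run the full retrieval benchmark
#'
#' The complete evaluation protocol over a labelled corpus: for every
#' condition x backend x imbalance-ratio x chunking combination, split the
#' condition's annotated series into reference and comparison sets, subsample
#' the irrelevant pool to the ratio, rank the pooled candidates against the
#' reference set, and score the ranking. Each cell's seed is derived by
#' hashing the master seed with the cell coordinates, so any cell is
#' independently reproducible.
#'
#' @param series A labelled series tibble.
#' @param backends Character vector of backend ids.
#' @param conditions Condition names; default: every label with at least 2
#'   annotated series.
#' @param ratios List of imbalance ratios (positive integers and/or
#'   `"all"`).
#' @param chunking Logical vector of chunking settings to cross
#'   (default `FALSE`).
#' @param seed Master integer seed.
#' @param dim Embedding dimension for `hashed_tfidf`.
#' @return A `geo_benchmark` tibble: one row per cell with columns
#'   `condition`, `backend_id`, `ratio`, `chunking`, `auprc`, `recall_10`,
#'   `recall_100`, `recall_1000`, `n_relevant`, `n_candidates`, `cell_seed`.
#' @export
run_benchmark <- function(series, backends, conditions = NULL,
                          ratios = list(1, "all"), chunking = FALSE,
                          seed = 1, dim = 256) {
  check_series(series)
  labels <- series$condition_labels
  all_labels <- sort(unique(unlist(labels, use.names = FALSE)))
  counts <- vapply(all_labels, function(cc) {
    sum(vapply(labels, function(l) cc %in% l, logical(1)))
  }, integer(1))
  if (is.null(conditions)) {
    conditions <- all_labels[counts >= 2]
  } else {
    few <- conditions[!(conditions %in% all_labels[counts >= 2])]
    if (length(few)) {
      abort(sprintf("condition(s) with fewer than 2 annotated series: %s",
                    paste(few, collapse = ", ")))
    }
  }
  if (!length(conditions)) abort("no condition has at least 2 annotated series")
  for (b in backends) backend_family(b)

  all_pool <- series$accession
  grid <- tidyr::expand_grid(
    condition = conditions,
    backend_id = backends,
    ratio = vapply(ratios, format, character(1)),
    chunking = chunking
  )
  cells <- purrr::pmap(grid, function(condition, backend_id, ratio, chunking) {
    cell_seed <- derive_seed(seed, condition, backend_id, ratio, chunking)
    annotated <- series$accession[vapply(labels, function(l) condition %in% l,
                                         logical(1))]
    plan <- make_split(annotated, all_pool, condition, cell_seed)
    pool_b <- subsample_imbalance(
      plan$comparison_b, length(plan$comparison_a),
      if (identical(ratio, "all")) "all" else as.integer(ratio),
      derive_seed(seed, condition, backend_id, ratio, chunking, "pool")
    )
    keep <- series$accession %in% c(plan$reference, plan$comparison_a, pool_b)
    ranking <- rank_by_reference(
      series[keep, , drop = FALSE], plan$reference, backend_id,
      config = chunking_config(enabled = chunking),
      condition = condition, dim = dim
    )
    rec <- recall_at_n(ranking, c(10, 100, 1000))
    tibble(
      condition = condition, backend_id = backend_id, ratio = ratio,
      chunking = chunking,
      auprc = precision_recall_auc(ranking),
      recall_10 = rec[1], recall_100 = rec[2], recall_1000 = rec[3],
      n_relevant = sum(ranking$relevant),
      n_candidates = nrow(ranking),
      cell_seed = cell_seed
    )
  })
  out <- dplyr::bind_rows(cells)
  structure(out, seed = seed, class = c("geo_benchmark", class(out)))
}
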