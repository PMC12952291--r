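#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a ranking
#'
#' Returns the ranking entries as a plain tibble (`rank`, `accession`,
#' `score`, `relevant`, `flagged`).
#'
#' @param x A `geo_ranking` from [rank_by_reference()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.geo_ranking <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row summary of a ranking
#'
#' Reports the backend, candidate counts, and — when relevance labels are
#' known — the AUPRC and recall at 10/100/1000.
#'
#' @param x A `geo_ranking`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.geo_ranking <- function(x, ...) {
  base <- tibble(
    condition = attr(x, "condition") %||% NA_character_,
    backend_id = attr(x, "backend_id"),
    n_candidates = nrow(x),
    n_flagged = sum(x$flagged)
  )
  if (!anyNA(x$relevant) && any(x$relevant) && !all(x$relevant)) {
    rec <- recall_at_n(x, c(10, 100, 1000))
    base$n_relevant <- sum(x$relevant)
    base$auprc <- precision_recall_auc(x)
    base$recall_10 <- rec[1]
    base$recall_100 <- rec[2]
    base$recall_1000 <- rec[3]
  }
  base
}

#' Tidy a benchmark result table
#'
#' @param x A `geo_benchmark` from [run_benchmark()].
#' @param ... Unused.
#' @return The per-cell results as a plain tibble.
#' @export
tidy.geo_benchmark <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row-per-backend summary of a benchmark
#'
#' Median AUPRC and median model rank (see [median_rank_table()]) per
#' backend, computed at the smallest imbalance ratio present unless the
#' benchmark only holds one.
#'
#' @param x A `geo_benchmark`.
#' @param ... Unused.
#' @return A tibble with one row per backend.
#' @export
glance.geo_benchmark <- function(x, ...) {
  tab <- as_tibble(as.data.frame(x))
  med <- tab |>
    dplyr::group_by(.data$backend_id) |>
    dplyr::summarise(median_auprc = stats::median(.data$auprc), .groups = "drop")
  ranks <- tab |>
    dplyr::group_by(.data$condition, .data$backend_id) |>
    dplyr::summarise(auprc = stats::median(.data$auprc), .groups = "drop") |>
    median_rank_table()
  dplyr::left_join(med, ranks, by = "backend_id") |>
    dplyr::arrange(.data$median_rank)
}
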