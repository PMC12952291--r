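#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_line geom_point
#'   facet_wrap labs theme_bw
#' @export
ggplot2::autoplot

#' Precision-recall curve for a ranking
#'
#' Plots precision against recall as the ranked list is traversed, for a
#' ranking with known relevance labels; the average precision (AUPRC) is
#' shown in the subtitle.
#'
#' @param object A `geo_ranking` with known labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.geo_ranking <- function(object, ...) {
  l <- relevance_labels(object)
  if (anyNA(l)) abort("relevance labels must be known to plot a PR curve")
  dat <- tibble(
    recall = cumsum(l) / sum(l),
    precision = cumsum(l) / seq_along(l)
  )
  ggplot(dat, aes(x = .data$recall, y = .data$precision)) +
    geom_step(direction = "vh") +
    labs(
      x = "Recall", y = "Precision",
      title = sprintf("Precision-recall, %s", attr(object, "backend_id")),
      subtitle = sprintf("AUPRC (average precision) = %.3f",
                         precision_recall_auc(object))
    ) +
    theme_bw()
}

#' Benchmark AUPRC by imbalance ratio
#'
#' One line per backend, faceted by condition, with the imbalance ratio on
#' the x axis in increasing order of pool size (`"all"` last) — the view
#' that shows how performance degrades as irrelevant candidates pile up.
#'
#' @param object A `geo_benchmark` from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.geo_benchmark <- function(object, ...) {
  tab <- as_tibble(as.data.frame(object))
  lev <- unique(tab$ratio)
  num <- suppressWarnings(as.numeric(lev))
  lev <- c(lev[!is.na(num)][order(num[!is.na(num)])], lev[is.na(num)])
  tab$ratio <- factor(tab$ratio, levels = lev)
  ggplot(tab, aes(x = .data$ratio, y = .data$auprc,
                  colour = .data$backend_id, group = .data$backend_id)) +
    geom_line() +
    geom_point() +
    facet_wrap(~condition) +
    labs(x = "Imbalance ratio (irrelevant : relevant)", y = "AUPRC",
         colour = "Backend") +
    theme_bw()
}
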