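#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a driver ranking
#'
#' @param x A `driver_ranking`.
#' @param ... Unused.
#' @return A plain tibble with one row per ranked gene.
#' @method tidy driver_ranking
#' @export
tidy.driver_ranking <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a driver ranking
#'
#' @param x A `driver_ranking`.
#' @param ... Unused.
#' @return A tibble with columns `n_ranked`, `top_gene`, `top_score`,
#'   `median_score`, `n_both_role`.
#' @method glance driver_ranking
#' @export
glance.driver_ranking <- function(x, ...) {
  tibble::tibble(
    n_ranked = nrow(x),
    top_gene = x$gene[1],
    top_score = x$score[1],
    median_score = stats::median(x$score),
    n_both_role = sum(x$role == "BOTH"))
}

#' Tidy an evaluation curve
#'
#' @param x A `driver_evaluation`.
#' @param ... Unused.
#' @return A long tibble with columns `k`, `metric`, `value`.
#' @method tidy driver_evaluation
#' @export
tidy.driver_evaluation <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"k",
                      names_to = "metric", values_to = "value")
}

#' One-row summary of an evaluation curve
#'
#' @param x A `driver_evaluation`.
#' @param ... Unused.
#' @return A tibble with `max_k`, `benchmark_size`, `best_f1`, `best_f1_k`,
#'   and the final precision/recall.
#' @method glance driver_evaluation
#' @export
glance.driver_evaluation <- function(x, ...) {
  i <- which.max(x$f1)
  tibble::tibble(
    max_k = max(x$k),
    benchmark_size = attr(x, "benchmark_size"),
    best_f1 = x$f1[i],
    best_f1_k = x$k[i],
    final_precision = x$precision[nrow(x)],
    final_recall = x$recall[nrow(x)])
}

#' Plot precision, recall and F1 against the top-k cutoff
#'
#' @param object A `driver_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot driver_evaluation
#' @export
autoplot.driver_evaluation <- function(object, ...) {
  ggplot2::ggplot(tidy.driver_evaluation(object),
                  ggplot2::aes(x = .data$k, y = .data$value,
                               colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "top-k cutoff", y = "score", colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the driver-score profile of a ranking
#'
#' Scores are shown on a log10 axis because semi-local scores of hubs exceed
#' those of peripheral genes by orders of magnitude.
#'
#' @param object A `driver_ranking`.
#' @param top Optional: show only the top `top` genes.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot driver_ranking
#' @export
autoplot.driver_ranking <- function(object, top = NULL, ...) {
  dat <- tibble::as_tibble(object)
  if (!is.null(top)) dat <- dplyr::slice_head(dat, n = top)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank, y = .data$score,
                                    colour = .data$role)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank", y = "semi-local driver score", colour = "role") +
    ggplot2::theme_minimal()
}

#' @export
plot.driver_evaluation <- function(x, ...) print(autoplot.driver_evaluation(x, ...))

#' @export
plot.driver_ranking <- function(x, ...) print(autoplot.driver_ranking(x, ...))
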