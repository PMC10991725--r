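#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_vline
#'   labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot the silhouette model-selection curve
#'
#' Overall silhouette against the number of clusters, with the selected
#' best k marked.
#'
#' @param object A `k_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.k_sweep <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$k, y = .data$silhouette)) +
    geom_line(colour = "grey40") +
    geom_point(size = 0.8) +
    geom_vline(xintercept = object$best_k, colour = "red",
               linetype = "dashed") +
    labs(x = "number of clusters (k)", y = "mean silhouette",
         title = sprintf("Silhouette sweep: best k = %d (score %.3f)",
                         object$best_k, object$best_score)) +
    theme_minimal()
}

#' Plot the topic-number coherence curve
#'
#' Average UMass coherence over clusters against the candidate topic
#' number, with the selected (most negative) value marked.
#'
#' @param object A `topic_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.topic_sweep <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$n_topics, y = .data$mean_coherence)) +
    geom_line(colour = "grey40") +
    geom_point() +
    geom_vline(xintercept = object$selected_t, colour = "red",
               linetype = "dashed") +
    labs(x = "number of topics", y = "mean UMass coherence",
         title = sprintf("Coherence sweep: selected T = %d",
                         object$selected_t)) +
    theme_minimal()
}

#' Plot publications per year for selected theme clusters
#'
#' @param trends A `trend_series` tibble from [trend_series()].
#' @param clusters Optional cluster ids to show (default: all).
#' @return A ggplot with one line per cluster.
#' @export
plot_trends <- function(trends, clusters = NULL) {
  dat <- trends
  if (!is.null(clusters)) {
    dat <- dat |> filter(.data$cluster_id %in% clusters)
  }
  ggplot(dat, aes(x = .data$year, y = .data$n,
                  colour = factor(.data$cluster_id))) +
    geom_line() +
    labs(x = "publication year", y = "publications",
         colour = "cluster") +
    theme_minimal()
}
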