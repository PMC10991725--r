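# broom-style tidiers for the fitted objects.

#' Tidy a fitted k-means theme model
#'
#' One row per cluster with its size.
#' @param x A `theme_kmeans`.
#' @param ... Unused.
#' @return A tibble with `cluster_id`, `size`.
#' @export
tidy.theme_kmeans <- function(x, ...) {
  tibble(cluster_id = seq_len(x$k) - 1L,
         size = tabulate(x$assignments + 1L, nbins = x$k))
}

#' One-row summary of a k-means fit
#' @param x A `theme_kmeans`.
#' @param ... Unused.
#' @return A tibble with `k`, `inertia`, `n_iter_run`, `converged`.
#' @export
glance.theme_kmeans <- function(x, ...) {
  tibble(k = x$k, inertia = x$inertia, n_iter_run = x$n_iter_run,
         converged = x$converged)
}

#' Tidy a silhouette result (per-cluster means)
#' @param x A `silhouette_result`.
#' @param ... Unused.
#' @export
tidy.silhouette_result <- function(x, ...) x$per_cluster

#' One-row summary of a silhouette result
#' @param x A `silhouette_result`.
#' @param ... Unused.
#' @export
glance.silhouette_result <- function(x, ...) {
  tibble(overall = x$overall, n_clusters = nrow(x$per_cluster))
}

#' Tidy a k sweep (the full score curve)
#' @param x A `k_sweep`.
#' @param ... Unused.
#' @export
tidy.k_sweep <- function(x, ...) x$curve

#' One-row summary of a k sweep
#' @param x A `k_sweep`.
#' @param ... Unused.
#' @export
glance.k_sweep <- function(x, ...) {
  tibble(best_k = x$best_k, best_silhouette = x$best_score,
         n_k_tried = nrow(x$curve))
}

#' Tidy an LDA model: topic-term probabilities in long form
#' @param x An `lda_model`.
#' @param n_terms Top terms per topic to keep (default 10).
#' @param ... Unused.
#' @return Tibble with `topic`, `term`, `probability`.
#' @export
tidy.lda_model <- function(x, n_terms = 10, ...) {
  purrr::map_dfr(seq_len(x$n_topics), function(t) {
    terms <- topic_top_words(x, t, min(n_terms, length(x$features)))
    tibble(topic = t, term = terms,
           probability = unname(x$topic_word[t, terms]))
  })
}

#' One-row summary of an LDA model
#' @param x An `lda_model`.
#' @param ... Unused.
#' @export
glance.lda_model <- function(x, ...) {
  tibble(n_topics = x$n_topics, n_features = length(x$features),
         n_docs = nrow(x$doc_topic))
}

#' Tidy a topic sweep (mean coherence per candidate T)
#' @param x A `topic_sweep`.
#' @param ... Unused.
#' @export
tidy.topic_sweep <- function(x, ...) x$curve

#' One-row summary of a topic sweep
#' @param x A `topic_sweep`.
#' @param ... Unused.
#' @export
glance.topic_sweep <- function(x, ...) {
  tibble(selected_t = x$selected_t,
         coherence_at_selected =
           x$curve$mean_coherence[x$curve$n_topics == x$selected_t])
}

#' Tidy a label-overlap evaluation (per-cluster fractions)
#' @param x A `label_overlap`.
#' @param ... Unused.
#' @export
tidy.label_overlap <- function(x, ...) x$per_cluster

#' One-row summary of a label-overlap evaluation
#' @param x A `label_overlap`.
#' @param ... Unused.
#' @export
glance.label_overlap <- function(x, ...) x$summary

#' Tidy a prediction result (per-record assignments)
#' @param x A `prediction_result`.
#' @param ... Unused.
#' @export
tidy.prediction_result <- function(x, ...) x$assignments

#' One-row summary of a prediction result
#' @param x A `prediction_result`.
#' @param ... Unused.
#' @export
glance.prediction_result <- function(x, ...) {
  tibble(n_records = nrow(x$assignments), n_nonempty = x$n_nonempty,
         mean_per_nonempty = x$mean_per_nonempty,
         median_per_nonempty = x$median_per_nonempty)
}

#' @export
print.theme_kmeans <- function(x, ...) {
  cat(sprintf("<theme_kmeans> k = %d, inertia = %.4g, %s after %d iteration(s)\n",
              x$k, x$inertia,
              if (isTRUE(x$converged)) "converged" else "not converged",
              x$n_iter_run))
  invisible(x)
}

#' @export
print.k_sweep <- function(x, ...) {
  cat(sprintf("<k_sweep> %d values of k; best k = %d (silhouette %.4f)\n",
              nrow(x$curve), x$best_k, x$best_score))
  invisible(x)
}

#' @export
print.topic_sweep <- function(x, ...) {
  cat(sprintf("<topic_sweep> T in %d..%d; selected T = %d\n",
              min(x$curve$n_topics), max(x$curve$n_topics), x$selected_t))
  invisible(x)
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf(
    "<model_bundle %s> %d docs, vocab %d, d = %d, k = %d, T = %d\n",
    x$config_hash, x$tfidf_model$n_docs_fit,
    nrow(x$tfidf_model$vocabulary), x$lsa_model$d,
    x$kmeans_model$k, x$topic_sweep$selected_t))
  invisible(x)
}
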