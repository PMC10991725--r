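#' Assign new publications to a fitted theme model
#'
#' Embeds new records with the frozen preprocessing, tf-idf and LSA models
#' and assigns each to the nearest k-means centroid (Euclidean distance,
#' ties to the lowest cluster id) — the model-inference step that keeps a
#' fitted theme map up to date as new literature appears. No model
#' component is refitted. Records whose text is entirely out of vocabulary
#' embed to the zero vector; they are still assigned (to the centroid
#' nearest the origin) and flagged.
#'
#' @param new_corpus Corpus tibble of new records.
#' @param tfidf_model Frozen `tfidf_model`.
#' @param lsa_model Frozen `lsa_model`.
#' @param kmeans_model Frozen `theme_kmeans`.
#' @param lemmatizer Plugin or name; must match the fit-time choice.
#' @return An object of class `prediction_result`: `assignments` tibble
#'   (`id`, `cluster_id`, `zero_vector`), `increments` tibble
#'   (`cluster_id`, `n`), `n_nonempty`, `mean_per_nonempty`,
#'   `median_per_nonempty`.
#' @export
predict_clusters <- function(new_corpus, tfidf_model, lsa_model,
                             kmeans_model, lemmatizer = "builtin") {
  stopifnot(inherits(tfidf_model, "tfidf_model"),
            inherits(lsa_model, "lsa_model"),
            inherits(kmeans_model, "theme_kmeans"))
  validate_corpus(new_corpus, "new_corpus")
  if (ncol(kmeans_model$centroids) != lsa_model$d) {
    stop_litthemes("centroid dimension does not match the LSA dimension",
                   "litthemes_dimension_error")
  }
  if (nrow(new_corpus) == 0) {
    return(structure(
      list(assignments = tibble(id = character(), cluster_id = integer(),
                                zero_vector = logical()),
           increments = tibble(cluster_id = integer(), n = integer()),
           n_nonempty = 0L, mean_per_nonempty = 0,
           median_per_nonempty = 0),
      class = "prediction_result"))
  }
  toks <- tokenize_corpus(new_corpus, lemmatizer)
  Xt <- transform_tfidf(tfidf_model, toks)
  zero <- Matrix::rowSums(Xt^2) == 0
  R <- transform_lsa(lsa_model, Xt)
  d2 <- cross_dist2(R, kmeans_model$centroids)
  cl <- max.col(-d2, ties.method = "first") - 1L
  assignments <- tibble(id = new_corpus$id, cluster_id = cl,
                        zero_vector = unname(zero))
  increments <- assignments |> count(.data$cluster_id, name = "n")
  structure(
    list(assignments = assignments, increments = increments,
         n_nonempty = nrow(increments),
         mean_per_nonempty = nrow(assignments) / nrow(increments),
         median_per_nonempty = stats::median(increments$n)),
    class = "prediction_result")
}
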