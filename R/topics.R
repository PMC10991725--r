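#' Bag-of-features for one cluster: lemma unigrams and ordered lemma pairs
#'
#' Builds the per-document count matrix the cluster-level topic model is
#' fitted on. Features are all word-token lemmas occurring in the cluster
#' plus all ordered pairs of adjacent word tokens; punctuation, number and
#' symbol tokens are excluded from both and break bigram adjacency (a pair
#' never spans an excluded token). Bigrams are underscore-joined strings.
#'
#' @param tokens_list List of lemma vectors, one per document of the
#'   cluster (in order).
#' @param doc_ids Optional document ids (defaults to positions).
#' @return An object of class `bag_of_features`: `counts` (sparse docs x
#'   features matrix), `features`, `doc_freq` (documents containing each
#'   feature), `n_docs`.
#' @examples
#' build_cluster_bow(list(c("colistin", "resistance")))$features
#' @export
build_cluster_bow <- function(tokens_list, doc_ids = NULL) {
  if (length(tokens_list) == 0) {
    stop_litthemes("cluster must contain at least one document",
                   "litthemes_parameter_error")
  }
  doc_ids <- doc_ids %||% as.character(seq_along(tokens_list))
  feats_per_doc <- purrr::map(tokens_list, function(tk) {
    word <- is_word_token(tk)
    runs <- split(tk[word], cumsum(!word)[word])
    unis <- tk[word]
    bis <- unlist(purrr::map(runs, function(r) {
      if (length(r) < 2) character(0) else
        paste(r[-length(r)], r[-1], sep = "_")
    }), use.names = FALSE)
    c(unis, bis)
  })
  features <- sort(unique(unlist(feats_per_doc, use.names = FALSE)),
                   method = "radix")
  if (length(features) == 0) {
    stop_litthemes("cluster documents contain no word tokens",
                   "litthemes_fit_error")
  }
  lens <- lengths(feats_per_doc)
  i <- rep.int(seq_along(feats_per_doc), lens)
  j <- match(unlist(feats_per_doc, use.names = FALSE), features)
  counts <- Matrix::sparseMatrix(
    i = i, j = j, x = rep(1, length(j)),
    dims = c(length(tokens_list), length(features)),
    dimnames = list(doc_ids, features))
  counts <- methods::as(counts, "CsparseMatrix")
  structure(
    list(counts = counts, features = features,
         doc_freq = Matrix::colSums(counts > 0), n_docs = nrow(counts)),
    class = "bag_of_features")
}

#' Topic-model configuration
#'
#' Priors and sampler settings for the per-cluster LDA fits. `alpha =
#' "auto"` uses the conventional symmetric document-topic prior `50 / T`;
#' `beta` is the symmetric topic-word prior. Coherence uses the `top_m`
#' highest-probability features of each topic with additive smoothing
#' `epsilon`.
#'
#' @param alpha `"auto"` (50/T) or a positive number.
#' @param beta Topic-word prior (default 0.01).
#' @param gibbs_iters Gibbs sweeps (default 1000).
#' @param coherence_top_m Words per topic entering the coherence score
#'   (default 10).
#' @param epsilon Coherence smoothing constant (default 1).
#' @param seed RNG seed for the sampler.
#' @return A list of class `topic_config`.
#' @export
topic_config <- function(alpha = "auto", beta = 0.01, gibbs_iters = 1000,
                         coherence_top_m = 10, epsilon = 1, seed = 1) {
  if (!identical(alpha, "auto") && (!is.numeric(alpha) || alpha <= 0)) {
    stop_litthemes("alpha must be \"auto\" or a positive number",
                   "litthemes_parameter_error")
  }
  stopifnot(beta > 0, gibbs_iters >= 1, coherence_top_m >= 1, epsilon > 0)
  structure(list(alpha = alpha, beta = beta, gibbs_iters = gibbs_iters,
                 coherence_top_m = coherence_top_m, epsilon = epsilon,
                 seed = seed),
            class = "topic_config")
}

resolve_alpha <- function(alpha, n_topics) {
  if (identical(alpha, "auto")) 50 / n_topics else alpha
}

#' Fit LDA by collapsed Gibbs sampling
#'
#' Samples token-level topic assignments with the collapsed Gibbs update
#' `P(z_i = k) ∝ (n_dk + α) (n_kw + β) / (n_k + Fβ)` and
#' takes point estimates from the final state:
#' `topic_word = (n_kw + β) / (n_k + Fβ)` and
#' `doc_topic = (n_dk + α) / (n_d + Tα)`. Seeded and
#' bit-reproducible.
#'
#' @param bow A `bag_of_features`.
#' @param n_topics Number of topics `T >= 1`.
#' @param config A [topic_config()].
#' @param check_counts Verify count conservation after every sweep
#'   (testing aid; default FALSE).
#' @return An object of class `lda_model`: `n_topics`, `topic_word` (T x F,
#'   rows sum to 1), `doc_topic` (n x T, rows sum to 1), `assignments`
#'   (final topic per token instance), `features`.
#' @export
lda_gibbs <- function(bow, n_topics, config = topic_config(),
                      check_counts = FALSE) {
  stopifnot(inherits(bow, "bag_of_features"), n_topics >= 1)
  F_ <- length(bow$features)
  if (n_topics > F_) {
    warn(sprintf("n_topics = %d exceeds the %d distinct features; proceeding",
                 n_topics, F_))
  }
  alpha <- resolve_alpha(config$alpha, n_topics)
  tm <- methods::as(bow$counts, "TsparseMatrix")
  ord <- order(tm@i, tm@j, method = "radix")
  reps <- as.integer(tm@x[ord])
  doc_id <- rep.int(tm@i[ord], reps)
  word_id <- rep.int(tm@j[ord], reps)
  if (length(doc_id) == 0) {
    stop_litthemes("bag of features is empty", "litthemes_fit_error")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  st <- .lda_gibbs_cpp(doc_id, word_id, bow$n_docs, F_, as.integer(n_topics),
                       alpha, config$beta, as.integer(config$gibbs_iters),
                       check_counts)
  topic_word <- (st$nkw + config$beta) /
    (st$nk + F_ * config$beta)
  colnames(topic_word) <- bow$features
  n_d <- Matrix::rowSums(bow$counts)
  doc_topic <- (st$ndk + alpha) / (n_d + n_topics * alpha)
  structure(
    list(n_topics = n_topics, topic_word = topic_word,
         doc_topic = doc_topic, assignments = st$z,
         features = bow$features, config = config),
    class = "lda_model")
}

#' UMass coherence of a topic's top words
#'
#' The document co-occurrence coherence
#' `C = sum_{i=2..M} sum_{j<i} ln((D(w_i, w_j) + eps) / D(w_j))`, where the
#' word list is ordered by descending topic probability and `D` counts the
#' documents of the reference collection containing the feature(s). More
#' negative values mean the top words co-occur more rarely.
#'
#' @param top_words Character vector of M features, most probable first.
#' @param bow The `bag_of_features` supplying document frequencies.
#' @param epsilon Smoothing constant (default 1).
#' @return A single numeric score (0 for M = 1).
#' @export
umass_coherence <- function(top_words, bow, epsilon = 1) {
  stopifnot(inherits(bow, "bag_of_features"), length(top_words) >= 1)
  m <- length(top_words)
  if (m == 1) return(0)
  idx <- match(top_words, bow$features)
  if (anyNA(idx)) {
    stop_litthemes(
      sprintf("word(s) not present in the reference collection: %s",
              paste(top_words[is.na(idx)], collapse = ", ")),
      "litthemes_contract_error")
  }
  present <- bow$counts[, idx, drop = FALSE] > 0
  present <- as.matrix(present)
  df <- colSums(present)
  if (any(df == 0)) {
    stop_litthemes("word with zero document frequency",
                   "litthemes_contract_error")
  }
  co <- crossprod(present)  # co[i, j] = D(w_i, w_j)
  score <- 0
  for (i in 2:m) {
    for (j in seq_len(i - 1)) {
      score <- score + log((co[i, j] + epsilon) / df[j])
    }
  }
  unname(score)
}

topic_top_words <- function(model, topic, m) {
  probs <- model$topic_word[topic, ]
  ord <- order(-probs, names(probs), method = "radix")
  names(probs)[utils::head(ord, m)]
}

#' Select the shared number of topics by coherence sweep
#'
#' For every cluster and every candidate topic number `T`, fits LDA and
#' records the mean UMass coherence over the `T` topics (using each
#' cluster's own documents as the co-occurrence reference); averages over
#' clusters per `T` (unweighted); and selects the `T` with the most
#' negative average, ties toward the smaller `T`. All clusters are then
#' refitted and described with the same selected `T`.
#'
#' @param cluster_bows Named list of `bag_of_features`, one per cluster.
#' @param t_min,t_max Sweep range (defaults 1, 10).
#' @param config A [topic_config()]; per-(cluster, T) seeds are derived
#'   from `config$seed`.
#' @return An object of class `topic_sweep`: `curve` (tibble `n_topics`,
#'   `mean_coherence`), `per_cluster` (tibble `cluster`, `n_topics`,
#'   `coherence`), `selected_t`, `models` (list of `lda_model` at
#'   `selected_t`, one per cluster).
#' @export
sweep_topics <- function(cluster_bows, t_min = 1, t_max = 10,
                         config = topic_config()) {
  stopifnot(length(cluster_bows) >= 1, t_min >= 1, t_max >= t_min)
  cluster_names <- names(cluster_bows) %||%
    as.character(seq_along(cluster_bows))
  ts <- seq(t_min, t_max)

  fit_one <- function(bow, n_topics, c_idx) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, c_idx * 1000L + n_topics)
    lda_gibbs(bow, n_topics, cfg)
  }
  cluster_coherence <- function(model, bow) {
    mean(vapply(seq_len(model$n_topics), function(t) {
      tw <- topic_top_words(model, t,
                            min(config$coherence_top_m,
                                length(model$features)))
      umass_coherence(tw, bow, config$epsilon)
    }, numeric(1)))
  }

  per_cluster <- purrr::map_dfr(seq_along(cluster_bows), function(ci) {
    purrr::map_dfr(ts, function(t) {
      model <- fit_one(cluster_bows[[ci]], t, ci)
      tibble(cluster = cluster_names[ci], n_topics = t,
             coherence = cluster_coherence(model, cluster_bows[[ci]]))
    })
  })
  curve <- per_cluster |>
    group_by(.data$n_topics) |>
    summarise(mean_coherence = mean(.data$coherence), .groups = "drop") |>
    arrange(.data$n_topics)
  selected_t <- curve$n_topics[which.min(curve$mean_coherence)]
  models <- purrr::map(seq_along(cluster_bows), function(ci) {
    fit_one(cluster_bows[[ci]], selected_t, ci)
  })
  names(models) <- cluster_names
  structure(
    list(curve = curve, per_cluster = per_cluster,
         selected_t = selected_t, models = models, config = config),
    class = "topic_sweep")
}

#' Representative terms of a fitted topic model
#'
#' Takes the `per_topic` highest-probability features of each topic in
#' topic order, concatenates them, and de-duplicates preserving first
#' occurrence — the per-cluster LDA term list (with six topics and two
#' terms each, at most 12 terms).
#'
#' @param model An `lda_model`.
#' @param per_topic Terms per topic (default 2).
#' @return Character vector of terms.
#' @export
representative_terms <- function(model, per_topic = 2) {
  stopifnot(inherits(model, "lda_model"))
  terms <- unlist(purrr::map(seq_len(model$n_topics), function(t) {
    topic_top_words(model, t, min(per_topic, length(model$features)))
  }), use.names = FALSE)
  unique(terms)
}
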