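BUNDLE_VERSION <- "litthemes_bundle_v1"

default_pipeline_config <- function() {
  list(
    seed = 1,
    preprocess = list(lemmatizer = "builtin"),
    vectorize = list(min_df = 1, keep_nonword = TRUE, normalize = TRUE,
                     d = 300),
    cluster = list(k_min = 50, k_max = 500, k_step = 1, max_iter = 300),
    topics = list(t_min = 1, t_max = 10, alpha = "auto", beta = 0.01,
                  gibbs_iters = 1000, coherence_top_m = 10, epsilon = 1,
                  per_topic_terms = 2),
    interpret = list(n_centroid_terms = 10)
  )
}

#' Assemble and validate a pipeline configuration
#'
#' Merges user settings over the pipeline defaults. Unknown keys (at the
#' top level or inside a stage) are rejected, so typos fail loudly rather
#' than silently falling back to defaults. The study-scale defaults are:
#' 300 LSA dimensions, k swept 50–500, topic number swept 1–10 with 1000
#' Gibbs sweeps, 10 centroid terms and 2 representative terms per topic.
#'
#' @param ... Named overrides, e.g. `cluster = list(k_min = 2, k_max = 10)`,
#'   `seed = 7`.
#' @return A validated config list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(cluster = list(k_min = 2, k_max = 10), seed = 42)
#' cfg$cluster$k_min
#' @export
pipeline_config <- function(...) {
  defaults <- default_pipeline_config()
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop_litthemes(sprintf("unknown config key(s): %s",
                           paste(unknown, collapse = ", ")),
                   "litthemes_config_error")
  }
  for (section in names(user)) {
    if (is.list(defaults[[section]])) {
      bad <- setdiff(names(user[[section]]), names(defaults[[section]]))
      if (length(bad) > 0) {
        stop_litthemes(
          sprintf("unknown config key(s) in '%s': %s", section,
                  paste(bad, collapse = ", ")),
          "litthemes_config_error")
      }
      defaults[[section]][names(user[[section]])] <- user[[section]]
    } else {
      defaults[[section]] <- user[[section]]
    }
  }
  structure(defaults, class = c("pipeline_config", "list"))
}

#' Fit the full theme-discovery pipeline
#'
#' Runs preprocess -> tf-idf -> LSA -> silhouette-selected k-means ->
#' per-cluster LDA with coherence-selected topic number -> term
#' extraction -> cluster descriptions, and returns everything needed to
#' describe the corpus and classify future records as a model bundle.
#' With `out_dir` set, the clustering and labelling tables and the two
#' model-selection curves are written as TSV (each stamped with the
#' effective-config hash) and the bundle is persisted in open text formats.
#'
#' @param corpus Corpus tibble.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return An object of class `model_bundle`.
#' @export
run_fit <- function(corpus, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_corpus(corpus)
  n_docs <- nrow(corpus)
  if (config$cluster$k_max > n_docs) {
    stop_litthemes(
      sprintf("cluster.k_max = %d exceeds the corpus size (%d)",
              config$cluster$k_max, n_docs),
      "litthemes_parameter_error")
  }

  toks <- tokenize_corpus(corpus, config$preprocess$lemmatizer)
  tfidf <- fit_tfidf(toks, min_df = config$vectorize$min_df,
                     keep_nonword = config$vectorize$keep_nonword,
                     normalize = config$vectorize$normalize)
  d_eff <- min(config$vectorize$d, n_docs, nrow(tfidf$vocabulary))
  config$vectorize$d_effective <- d_eff
  lsa <- fit_lsa(tfidf$matrix, d = d_eff)

  ksweep <- sweep_k(lsa$scores,
                    k_min = config$cluster$k_min,
                    k_max = config$cluster$k_max,
                    step = config$cluster$k_step,
                    max_iter = config$cluster$max_iter,
                    seed = config$seed)
  km <- ksweep$best_model
  assignments <- km$assignments

  cent_terms <- centroid_top_terms(assignments, tfidf$matrix,
                                   n = config$interpret$n_centroid_terms)

  cluster_ids <- sort(unique(assignments))
  bows <- purrr::map(cluster_ids, function(c_id) {
    build_cluster_bow(toks$tokens[assignments == c_id],
                      doc_ids = toks$id[assignments == c_id])
  })
  names(bows) <- as.character(cluster_ids)
  tcfg <- topic_config(alpha = config$topics$alpha,
                       beta = config$topics$beta,
                       gibbs_iters = config$topics$gibbs_iters,
                       coherence_top_m = config$topics$coherence_top_m,
                       epsilon = config$topics$epsilon,
                       seed = derive_seed(config$seed, 271L))
  tsweep <- sweep_topics(bows, t_min = config$topics$t_min,
                         t_max = config$topics$t_max, config = tcfg)
  lda_terms <- purrr::imap_dfr(tsweep$models, function(m, c_name) {
    tibble(cluster_id = as.integer(c_name),
           term = representative_terms(m, config$topics$per_topic_terms))
  })

  descriptions <- build_descriptions(corpus, assignments,
                                     lda_terms = lda_terms,
                                     centroid_terms = cent_terms)

  config_hash <- rlang::hash(unclass(config))
  bundle <- structure(
    list(version = BUNDLE_VERSION, config = config,
         config_hash = config_hash,
         lemmatizer = config$preprocess$lemmatizer,
         tfidf_model = tfidf, lsa_model = lsa, kmeans_model = km,
         k_sweep = structure(ksweep[c("curve", "best_k", "best_score")],
                             class = "k_sweep"),
         topic_sweep = structure(
           tsweep[c("curve", "per_cluster", "selected_t")],
           class = "topic_sweep"),
         lda_terms = lda_terms, centroid_terms = cent_terms,
         descriptions = descriptions,
         assignments = tibble(id = corpus$id, cluster_id = assignments)),
    class = "model_bundle")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_clustering_table(corpus, assignments, descriptions,
                           file.path(out_dir, "clustering_table.tsv"),
                           config_hash = config_hash)
    write_labelling_table(descriptions,
                          file.path(out_dir, "labelling_table.tsv"),
                          config_hash = config_hash)
    write_table_with_hash(ksweep$curve,
                          file.path(out_dir, "silhouette_curve.tsv"),
                          config_hash)
    write_table_with_hash(tsweep$curve,
                          file.path(out_dir, "coherence_curve.tsv"),
                          config_hash)
    save_model_bundle(bundle, file.path(out_dir, "model"))
  }
  bundle
}

#' Predict clusters for new records with a fitted bundle
#'
#' @param bundle A `model_bundle` from [run_fit()] or [load_model_bundle()].
#' @param new_corpus Corpus tibble of new records.
#' @param out_dir Optional directory for the prediction table and summary.
#' @return A `prediction_result` (see [predict_clusters()]); the written
#'   prediction table carries each record's predicted cluster and, when
#'   available, the cluster's manual label.
#' @export
run_predict <- function(bundle, new_corpus, out_dir = NULL) {
  if (!inherits(bundle, "model_bundle") ||
        !identical(bundle$version, BUNDLE_VERSION)) {
    stop_litthemes(
      sprintf("incompatible model bundle (expected version %s)",
              BUNDLE_VERSION),
      "litthemes_version_error")
  }
  pred <- predict_clusters(new_corpus, bundle$tfidf_model,
                           bundle$lsa_model, bundle$kmeans_model,
                           lemmatizer = bundle$lemmatizer)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    labels <- bundle$descriptions[, c("cluster_id", "label")]
    table_out <- new_corpus |>
      select("id", "title", "year") |>
      left_join(pred$assignments, by = "id") |>
      left_join(labels, by = "cluster_id")
    write_table_with_hash(table_out,
                          file.path(out_dir, "prediction_table.tsv"),
                          bundle$config_hash)
    write_table_with_hash(
      tibble(n_records = nrow(pred$assignments),
             n_nonempty = pred$n_nonempty,
             mean_per_nonempty = pred$mean_per_nonempty,
             median_per_nonempty = pred$median_per_nonempty),
      file.path(out_dir, "prediction_summary.tsv"),
      bundle$config_hash)
  }
  pred
}

fmt_num <- function(x) sprintf("%.17g", x)

write_numeric_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  readr::write_tsv(df, path)
}

read_numeric_tsv <- function(path, num_cols) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  for (col in intersect(num_cols, names(df))) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Persist a model bundle as a directory of open formats
#'
#' Writes the frozen vectorizer, LSA basis, centroids, assignments, term
#' lists and descriptions as TSV files plus a JSON manifest — inspectable,
#' language-agnostic artifacts rather than a native binary.
#'
#' @param bundle A `model_bundle`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "model_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    version = bundle$version, config = unclass(bundle$config),
    config_hash = bundle$config_hash, lemmatizer = bundle$lemmatizer,
    n_docs_fit = bundle$tfidf_model$n_docs_fit,
    normalize = bundle$tfidf_model$normalize,
    d = bundle$lsa_model$d,
    captured_variance = bundle$lsa_model$captured_variance,
    k = bundle$kmeans_model$k,
    best_k = bundle$k_sweep$best_k,
    best_silhouette = bundle$k_sweep$best_score,
    selected_t = bundle$topic_sweep$selected_t
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_numeric_tsv(bundle$tfidf_model$vocabulary,
                    file.path(dir, "vocabulary.tsv"))
  comp <- as_tibble(bundle$lsa_model$components, .name_repair = "minimal")
  names(comp) <- sprintf("c%03d", seq_len(ncol(comp)))
  comp <- dplyr::bind_cols(tibble(token = rownames(bundle$lsa_model$components)),
                           comp)
  write_numeric_tsv(comp, file.path(dir, "components.tsv"))
  write_numeric_tsv(tibble(singular_value = bundle$lsa_model$singular_values),
                    file.path(dir, "singular_values.tsv"))
  cent <- as_tibble(bundle$kmeans_model$centroids, .name_repair = "minimal")
  names(cent) <- sprintf("c%03d", seq_len(ncol(cent)))
  cent <- dplyr::bind_cols(
    tibble(cluster_id = seq_len(bundle$kmeans_model$k) - 1L), cent)
  write_numeric_tsv(cent, file.path(dir, "centroids.tsv"))
  readr::write_tsv(bundle$assignments, file.path(dir, "assignments.tsv"))
  readr::write_tsv(bundle$lda_terms, file.path(dir, "lda_terms.tsv"))
  write_numeric_tsv(bundle$centroid_terms,
                    file.path(dir, "centroid_terms.tsv"))
  write_labelling_table(bundle$descriptions,
                        file.path(dir, "descriptions.tsv"))
  write_numeric_tsv(bundle$k_sweep$curve,
                    file.path(dir, "silhouette_curve.tsv"))
  write_numeric_tsv(bundle$topic_sweep$curve,
                    file.path(dir, "coherence_curve.tsv"))
  invisible(dir)
}

#' Load a persisted model bundle
#'
#' Reconstructs the frozen models from a directory written by
#' [save_model_bundle()]. Loading a bundle and predicting the training
#' corpus reproduces the training assignments.
#'
#' @param dir Bundle directory.
#' @return A `model_bundle`.
#' @export
load_model_bundle <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop_litthemes(sprintf("'%s' is not a model bundle directory", dir),
                   "litthemes_io_error")
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (!identical(manifest$version, BUNDLE_VERSION)) {
    stop_litthemes(
      sprintf("bundle version '%s' does not match '%s'",
              manifest$version, BUNDLE_VERSION),
      "litthemes_version_error")
  }
  vocab <- read_numeric_tsv(file.path(dir, "vocabulary.tsv"), c("idf"))
  vocab$df <- as.integer(vocab$df)
  tfidf <- structure(
    list(vocabulary = as_tibble(vocab), n_docs_fit = manifest$n_docs_fit,
         normalize = manifest$normalize),
    class = "tfidf_model")
  comp_df <- read_numeric_tsv(file.path(dir, "components.tsv"),
                              sprintf("c%03d", seq_len(manifest$d)))
  comp <- as.matrix(comp_df[, -1])
  rownames(comp) <- comp_df$token
  storage.mode(comp) <- "double"
  sv <- read_numeric_tsv(file.path(dir, "singular_values.tsv"),
                         "singular_value")$singular_value
  lsa <- structure(
    list(d = manifest$d, components = comp, singular_values = sv,
         captured_variance = manifest$captured_variance),
    class = "lsa_model")
  cent_df <- read_numeric_tsv(file.path(dir, "centroids.tsv"),
                              sprintf("c%03d", seq_len(manifest$d)))
  cent <- as.matrix(cent_df[, -1])
  storage.mode(cent) <- "double"
  assignments <- readr::read_tsv(file.path(dir, "assignments.tsv"),
                                 col_types = "ci", progress = FALSE)
  km <- structure(
    list(k = manifest$k, centroids = cent,
         assignments = assignments$cluster_id,
         inertia = NA_real_, inertia_trace = numeric(0),
         n_iter_run = NA_integer_, converged = NA, seed = NULL),
    class = "theme_kmeans")
  lda_terms <- readr::read_tsv(file.path(dir, "lda_terms.tsv"),
                               col_types = "ic", progress = FALSE)
  centroid_terms <- read_numeric_tsv(file.path(dir, "centroid_terms.tsv"),
                                     "weight")
  centroid_terms$cluster_id <- as.integer(centroid_terms$cluster_id)
  centroid_terms$rank <- as.integer(centroid_terms$rank)
  desc_raw <- readr::read_tsv(file.path(dir, "descriptions.tsv"),
                              col_types = "iiciicc", comment = "#",
                              progress = FALSE)
  descriptions <- desc_raw |>
    mutate(
      label = ifelse(is.na(.data$label), NA_character_, .data$label),
      lda_terms = stringr::str_split(.data$lda_terms, stringr::fixed(" ")),
      centroid_terms = stringr::str_split(.data$centroid_terms,
                                          stringr::fixed(" "))
    )
  cfg <- manifest$config
  class(cfg) <- c("pipeline_config", "list")
  structure(
    list(version = manifest$version, config = cfg,
         config_hash = manifest$config_hash,
         lemmatizer = manifest$lemmatizer,
         tfidf_model = tfidf, lsa_model = lsa, kmeans_model = km,
         k_sweep = structure(list(
           curve = read_numeric_tsv(file.path(dir, "silhouette_curve.tsv"),
                                    "silhouette"),
           best_k = manifest$best_k,
           best_score = manifest$best_silhouette), class = "k_sweep"),
         topic_sweep = structure(list(
           curve = read_numeric_tsv(file.path(dir, "coherence_curve.tsv"),
                                    "mean_coherence"),
           selected_t = manifest$selected_t), class = "topic_sweep"),
         lda_terms = lda_terms, centroid_terms = centroid_terms,
         descriptions = descriptions, assignments = assignments),
    class = "model_bundle")
}
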