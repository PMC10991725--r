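#' Build per-cluster descriptions
#'
#' Combines cluster membership with the automatic term lists into one row
#' per theme cluster: size, publication-year span (min/max over members
#' with a known year), and the LDA and centroid term lists. The manual
#' label starts empty and can be merged in later with [merge_labels()].
#'
#' @param corpus Corpus tibble.
#' @param assignments 0-based cluster id per record.
#' @param lda_terms Named list (by cluster id) of LDA term vectors, or a
#'   tibble with `cluster_id`, `term`.
#' @param centroid_terms Tibble from [centroid_top_terms()], or a named
#'   list of term vectors.
#' @return Tibble with columns `cluster_id`, `size`, `label`,
#'   `start_year`, `end_year`, `lda_terms` (list), `centroid_terms` (list).
#' @export
build_descriptions <- function(corpus, assignments, lda_terms = NULL,
                               centroid_terms = NULL) {
  validate_corpus(corpus)
  assignments <- validate_assignments(assignments, nrow(corpus))
  lda_list <- as_term_list(lda_terms)
  cent_list <- as_term_list(centroid_terms)
  clusters <- sort(unique(assignments))
  purrr::map_dfr(clusters, function(c_id) {
    members <- which(assignments == c_id)
    yrs <- corpus$year[members]
    yrs <- yrs[!is.na(yrs)]
    tibble(
      cluster_id = c_id,
      size = length(members),
      label = NA_character_,
      start_year = if (length(yrs)) min(yrs) else NA_integer_,
      end_year = if (length(yrs)) max(yrs) else NA_integer_,
      lda_terms = list(lda_list[[as.character(c_id)]] %||% character(0)),
      centroid_terms = list(cent_list[[as.character(c_id)]] %||% character(0))
    )
  })
}

as_term_list <- function(x) {
  if (is.null(x)) return(list())
  if (is.data.frame(x)) {
    stopifnot(all(c("cluster_id", "term") %in% names(x)))
    return(split(x$term, x$cluster_id))
  }
  x
}

#' Merge manual labels into cluster descriptions
#'
#' @param descriptions Tibble from [build_descriptions()].
#' @param labels Tibble with columns `cluster_id`, `label` (e.g. read from
#'   a two-column delimited file).
#' @return The descriptions with the `label` column filled.
#' @export
merge_labels <- function(descriptions, labels) {
  stopifnot(all(c("cluster_id", "label") %in% names(labels)))
  descriptions |>
    select(-"label") |>
    left_join(labels[, c("cluster_id", "label")], by = "cluster_id") |>
    select("cluster_id", "size", "label", dplyr::everything())
}

#' Evaluate manual labels against the automatic term lists
#'
#' Normalises each manual label phrase (tokenize, lemmatize, lowercase,
#' drop stop words / punctuation / symbols) into a word set `P`, then
#' computes for every labelled cluster the term-side fractions
#' `|lda ∩ P| / |lda|` and `|centroid ∩ P| / |centroid|`, and the
#' phrase-side coverage `|P ∩ (lda ∩ centroid)| / |P|` by the terms shared
#' between both lists. Corpus-level summaries are unweighted means over
#' evaluated clusters. Both directions are reported because per-cluster
#' agreement reads naturally phrase-side while list-quality reads
#' term-side.
#'
#' @param descriptions Labelled descriptions ([merge_labels()]).
#' @param lemmatizer Plugin or name.
#' @param stopwords Character vector (default [english_stopwords()]).
#' @return An object of class `label_overlap`: `per_cluster` tibble
#'   (`cluster_id`, `lda_fraction`, `centroid_fraction`,
#'   `phrase_coverage`), and `summary` (one-row tibble of means).
#' @export
evaluate_label_overlap <- function(descriptions,
                                   lemmatizer = "builtin",
                                   stopwords = english_stopwords()) {
  labelled <- descriptions |> filter(!is.na(.data$label), .data$label != "")
  if (nrow(labelled) == 0) {
    stop_litthemes("no labelled clusters to evaluate",
                   "litthemes_parameter_error")
  }
  plugin <- resolve_lemmatizer(lemmatizer)
  rows <- purrr::pmap(labelled, function(cluster_id, label, lda_terms,
                                         centroid_terms, ...) {
    toks <- lemmatize(tokenize(label), plugin)
    p_set <- unique(setdiff(toks[is_word_token(toks)], stopwords))
    if (length(p_set) == 0) {
      warn(sprintf("label of cluster %s normalises to an empty set; excluded",
                   cluster_id))
      return(NULL)
    }
    lda <- unique(lda_terms)
    cent <- unique(centroid_terms)
    overlap <- intersect(lda, cent)
    tibble(
      cluster_id = cluster_id,
      n_phrase_words = length(p_set),
      lda_fraction = if (length(lda)) length(intersect(lda, p_set)) /
        length(lda) else NA_real_,
      centroid_fraction = if (length(cent)) length(intersect(cent, p_set)) /
        length(cent) else NA_real_,
      phrase_coverage = length(intersect(p_set, overlap)) / length(p_set)
    )
  })
  per_cluster <- bind_rows(purrr::compact(rows))
  if (nrow(per_cluster) == 0) {
    stop_litthemes("all labels normalised to empty sets",
                   "litthemes_parameter_error")
  }
  summary <- per_cluster |>
    summarise(
      n_clusters = n(),
      mean_lda_fraction = mean(.data$lda_fraction, na.rm = TRUE),
      mean_centroid_fraction = mean(.data$centroid_fraction, na.rm = TRUE),
      mean_phrase_coverage = mean(.data$phrase_coverage)
    )
  structure(list(per_cluster = per_cluster, summary = summary),
            class = "label_overlap")
}

#' Publications per theme per year
#'
#' Counts cluster members by publication year over the corpus year range
#' (each cluster's series is completed with zeros across the full range).
#' Records without a known year are excluded from the series and tallied
#' in the `missing_year` attribute; per-cluster series totals therefore
#' equal the count of members with a known year.
#'
#' @param corpus Corpus tibble.
#' @param assignments 0-based cluster id per record.
#' @return Tibble of class `trend_series` with columns `cluster_id`,
#'   `year`, `n`; attribute `missing_year` is a tibble of per-cluster
#'   counts of year-less records.
#' @export
trend_series <- function(corpus, assignments) {
  validate_corpus(corpus)
  assignments <- validate_assignments(assignments, nrow(corpus))
  dat <- tibble(cluster_id = assignments, year = corpus$year)
  missing <- dat |> filter(is.na(.data$year)) |> count(.data$cluster_id)
  known <- dat |> filter(!is.na(.data$year))
  if (nrow(known) == 0) {
    out <- tibble(cluster_id = integer(), year = integer(), n = integer())
  } else {
    out <- known |>
      count(.data$cluster_id, .data$year) |>
      tidyr::complete(
        cluster_id = sort(unique(assignments)),
        year = seq(min(known$year), max(known$year)),
        fill = list(n = 0L)) |>
      arrange(.data$cluster_id, .data$year)
  }
  attr(out, "missing_year") <- missing
  class(out) <- c("trend_series", class(out))
  out
}

#' Audit a keyword across clusters
#'
#' Finds every record mentioning a keyword, grouped by cluster with the
#' publication year and the field it appeared in — the audit behind
#' first-mention questions such as "was this antibiotic mentioned anywhere
#' before year Y?". Matching is case-insensitive; `substring` mode scans
#' the raw lowercased title/abstract, `lemma` mode matches whole lemmas
#' after tokenization.
#'
#' @param corpus Corpus tibble.
#' @param assignments 0-based cluster id per record.
#' @param keyword Non-empty search term.
#' @param mode `"substring"` (default) or `"lemma"`.
#' @param lemmatizer Plugin or name (lemma mode).
#' @return Tibble with columns `cluster_id`, `id`, `year`, `field`
#'   (`"title"` or `"abstract"`), one row per hit.
#' @export
keyword_search <- function(corpus, assignments, keyword,
                           mode = c("substring", "lemma"),
                           lemmatizer = "builtin") {
  mode <- match.arg(mode)
  validate_corpus(corpus)
  assignments <- validate_assignments(assignments, nrow(corpus))
  if (!nzchar(keyword)) {
    stop_litthemes("keyword must be non-empty", "litthemes_parameter_error")
  }
  kw <- tolower(keyword)
  hit_fun <- if (mode == "substring") {
    function(text) stringr::str_detect(tolower(text), stringr::fixed(kw))
  } else {
    plugin <- resolve_lemmatizer(lemmatizer)
    kw_lemma <- lemmatize(tokenize(kw), plugin)
    function(text) {
      lem <- lemmatize(tokenize(text), plugin)
      length(kw_lemma) > 0 && all(kw_lemma %in% lem) &&
        (length(kw_lemma) == 1 ||
           grepl(paste(kw_lemma, collapse = " "),
                 paste(lem, collapse = " "), fixed = TRUE))
    }
  }
  hits <- purrr::map_dfr(seq_len(nrow(corpus)), function(i) {
    fields <- c(
      if (isTRUE(hit_fun(corpus$title[i]))) "title",
      if (nzchar(corpus$abstract[i]) &&
            isTRUE(hit_fun(corpus$abstract[i]))) "abstract")
    if (length(fields) == 0) return(NULL)
    tibble(cluster_id = assignments[i], id = corpus$id[i],
           year = corpus$year[i], field = fields)
  })
  if (nrow(hits) == 0) {
    hits <- tibble(cluster_id = integer(), id = character(),
                   year = integer(), field = character())
  }
  attr(hits, "keyword") <- keyword
  attr(hits, "mode") <- mode
  hits |> arrange(.data$cluster_id, .data$year, .data$id)
}
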