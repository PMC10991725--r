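#' Specify a synthetic bibliographic corpus with planted themes
#'
#' Defines the generative conditions for a synthetic corpus: `n_themes`
#' disjoint signature vocabularies embedded in a shared Zipfian background
#' vocabulary. Each document draws its tokens i.i.d. — with probability
#' `signature_weight` uniformly from its theme's signature words, otherwise
#' from the background under a Zipf law — giving planted structure that
#' both document clustering (document-level separation) and topic models
#' (word co-occurrence) can recover with analytically known parameters.
#' Title/abstract lengths, years (uniform in per-theme windows, which can
#' emulate recently emergent or defunct themes) and journals complete the
#' bibliographic metadata.
#'
#' @param n_themes Number of planted themes (default 5).
#' @param docs_per_theme Documents per theme: one integer or a vector of
#'   length `n_themes` (default 40).
#' @param signature_vocab_size Signature words per theme (default 20).
#' @param background_vocab_size Shared background vocabulary size
#'   (default 500).
#' @param signature_weight Probability a token comes from the theme
#'   signature (default 0.7).
#' @param title_len_range,abstract_len_range Token-count ranges
#'   (defaults 5–15 and 50–200).
#' @param year_windows List of `c(start, end)` per theme; default spreads
#'   overlapping windows across 1990–2022.
#' @param journals Journal name pool.
#' @param zipf_exponent Background Zipf exponent (default 1.1).
#' @param seed RNG seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_themes = 5, docs_per_theme = 40,
                           signature_vocab_size = 20,
                           background_vocab_size = 500,
                           signature_weight = 0.7,
                           title_len_range = c(5, 15),
                           abstract_len_range = c(50, 200),
                           year_windows = NULL,
                           journals = sprintf("J Synth Res %d", 1:8),
                           zipf_exponent = 1.1,
                           seed = 1) {
  if (length(docs_per_theme) == 1) {
    docs_per_theme <- rep(docs_per_theme, n_themes)
  }
  stopifnot(n_themes >= 1, length(docs_per_theme) == n_themes,
            all(docs_per_theme >= 1),
            signature_weight > 0, signature_weight < 1,
            signature_vocab_size >= 1, background_vocab_size >= 1)
  if (is.null(year_windows)) {
    starts <- round(seq(1990, 2012, length.out = n_themes))
    year_windows <- purrr::map(starts, function(s) c(s, 2022))
  }
  stopifnot(length(year_windows) == n_themes)
  structure(
    list(n_themes = n_themes, docs_per_theme = docs_per_theme,
         signature_vocab_size = signature_vocab_size,
         background_vocab_size = background_vocab_size,
         signature_weight = signature_weight,
         title_len_range = title_len_range,
         abstract_len_range = abstract_len_range,
         year_windows = year_windows, journals = journals,
         zipf_exponent = zipf_exponent, seed = seed),
    class = "synthetic_spec")
}

#' Generate a synthetic corpus with gold theme labels
#'
#' Draws a corpus from a [synthetic_spec()], fully reproducible from the
#' spec's seed. Signature vocabularies are pairwise disjoint by
#' construction (`t<theme>w<index>`); background words (`bg<index>`) follow
#' a Zipf law. All generated words are lemma-stable under the built-in
#' lemmatizer, so the planted structure survives preprocessing intact.
#'
#' @param spec A `synthetic_spec`.
#' @return A list with `corpus` (tibble: id, title, abstract, year, date,
#'   journal), `gold` (tibble: id, theme), and `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  signatures <- purrr::map(seq_len(spec$n_themes), function(t) {
    sprintf("t%02dw%02d", t, seq_len(spec$signature_vocab_size))
  })
  if (anyDuplicated(unlist(signatures))) {
    stop_litthemes("signature vocabularies overlap", "litthemes_spec_error")
  }
  background <- sprintf("bg%03d", seq_len(spec$background_vocab_size))
  zipf_p <- seq_len(spec$background_vocab_size)^(-spec$zipf_exponent)
  zipf_p <- zipf_p / sum(zipf_p)

  set.seed(spec$seed)
  rows <- purrr::map_dfr(seq_len(spec$n_themes), function(t) {
    n_docs <- spec$docs_per_theme[t]
    purrr::map_dfr(seq_len(n_docs), function(d) {
      n_title <- sample(spec$title_len_range[1]:spec$title_len_range[2], 1)
      n_abs <- sample(spec$abstract_len_range[1]:spec$abstract_len_range[2], 1)
      n_tok <- n_title + n_abs
      from_sig <- runif(n_tok) < spec$signature_weight
      toks <- character(n_tok)
      toks[from_sig] <- sample(signatures[[t]], sum(from_sig),
                               replace = TRUE)
      toks[!from_sig] <- sample(background, sum(!from_sig),
                                replace = TRUE, prob = zipf_p)
      win <- spec$year_windows[[t]]
      year <- sample(win[1]:win[2], 1)
      tibble(
        id = sprintf("syn-t%02d-%04d", t, d),
        title = paste(toks[seq_len(n_title)], collapse = " "),
        abstract = paste(toks[(n_title + 1):n_tok], collapse = " "),
        year = as.integer(year),
        date = sprintf("%d-01-01", year),
        journal = sample(spec$journals, 1),
        theme = t
      )
    })
  })
  corpus <- rows |> select(-"theme")
  attr(corpus, "provenance") <- sprintf(
    "synthetic corpus: %d themes, seed %d", spec$n_themes, spec$seed)
  validate_corpus(corpus)
  list(corpus = corpus,
       gold = tibble(id = rows$id, theme = rows$theme),
       spec = spec)
}

#' Score cluster recovery against the planted themes
#'
#' Compares a clustering of a synthetic corpus against the gold theme
#' labels: Adjusted Rand Index, cluster purity (fraction of documents in
#' their cluster's majority theme), and accuracy after mapping each
#' cluster to its majority theme.
#'
#' @param gold Gold tibble from [generate_corpus()] (columns `id`,
#'   `theme`), ordered as the corpus.
#' @param assignments 0-based cluster id per record, in corpus order.
#' @return One-row tibble with `ari`, `purity`, `majority_accuracy`.
#' @export
score_recovery <- function(gold, assignments) {
  assignments <- validate_assignments(assignments, nrow(gold))
  tab <- table(assignments, gold$theme)
  purity <- sum(apply(tab, 1, max)) / length(assignments)
  majority <- colnames(tab)[apply(tab, 1, which.max)]
  mapped <- majority[match(assignments, as.integer(rownames(tab)))]
  tibble(
    ari = mclust::adjustedRandIndex(assignments, gold$theme),
    purity = purity,
    majority_accuracy = mean(mapped == as.character(gold$theme))
  )
}
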