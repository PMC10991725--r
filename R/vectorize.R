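#' Fit the tf-idf vectorizer
#'
#' Builds the token vocabulary over a tokenized corpus and computes the
#' document-term matrix under the smoothed tf-idf weighting
#' `tf(d,t) * (ln((1 + N) / (1 + df(t))) + 1)` with raw term counts and
#' (by default) L2 row normalization — the convention of the mainstream
#' machine-learning vectorizers, so a fitted model transfers across
#' toolchains. The vocabulary keeps every token with document frequency at
#' least `min_df`; punctuation/number/symbol tokens are kept unless
#' `keep_nonword = FALSE`.
#'
#' @param tokens_tbl Tibble with columns `id`, `tokens` from
#'   [tokenize_corpus()].
#' @param min_df Minimum document frequency for a token to enter the
#'   vocabulary (default 1: no pruning).
#' @param keep_nonword Keep punctuation/number/symbol tokens (default TRUE).
#' @param normalize L2-normalise rows (default TRUE).
#' @return An object of class `tfidf_model` with elements `vocabulary`
#'   (tibble: token, df, idf), `n_docs_fit`, `normalize`, and `matrix`, the
#'   fit-time sparse tf-idf matrix (docs x vocabulary, `dgCMatrix`).
#' @examples
#' toks <- tibble::tibble(id = c("d1", "d2"),
#'                        tokens = list(c("a", "b"), "a"))
#' fit_tfidf(toks)$vocabulary
#' @export
fit_tfidf <- function(tokens_tbl, min_df = 1, keep_nonword = TRUE,
                      normalize = TRUE) {
  stopifnot(is.data.frame(tokens_tbl), all(c("id", "tokens") %in%
                                             names(tokens_tbl)))
  if (nrow(tokens_tbl) == 0) {
    stop_litthemes("cannot fit tf-idf on an empty corpus",
                   "litthemes_fit_error")
  }
  if (min_df < 1) {
    stop_litthemes("min_df must be >= 1", "litthemes_parameter_error")
  }
  n_docs <- nrow(tokens_tbl)
  uniq <- purrr::map(tokens_tbl$tokens, unique)
  all_tokens <- unlist(uniq, use.names = FALSE)
  if (length(all_tokens) == 0) {
    stop_litthemes("all documents are empty; cannot fit tf-idf",
                   "litthemes_fit_error")
  }
  df_tab <- table(all_tokens)
  vocab <- tibble(token = names(df_tab), df = as.integer(df_tab))
  if (!keep_nonword) {
    vocab <- vocab[is_word_token(vocab$token), ]
  }
  vocab <- vocab[vocab$df >= min_df, ]
  if (nrow(vocab) == 0) {
    stop_litthemes(
      sprintf("min_df = %d leaves an empty vocabulary (N = %d docs)",
              min_df, n_docs),
      "litthemes_fit_error")
  }
  vocab <- vocab[order(vocab$token, method = "radix"), ]
  vocab$idf <- log((1 + n_docs) / (1 + vocab$df)) + 1

  model <- structure(
    list(vocabulary = vocab, n_docs_fit = n_docs, normalize = normalize),
    class = "tfidf_model")
  model$matrix <- transform_tfidf(model, tokens_tbl)
  model
}

#' Embed documents with a frozen tf-idf model
#'
#' Applies the fit-time vocabulary and idf weights to new tokenized
#' documents. Out-of-vocabulary tokens are dropped silently; a document
#' with no in-vocabulary tokens yields a zero row (reported via message,
#' not an error).
#'
#' @param model A fitted `tfidf_model`.
#' @param tokens_tbl Tibble with `id`, `tokens` columns.
#' @return Sparse `dgCMatrix`, one row per document in input order, columns
#'   the fit-time vocabulary.
#' @export
transform_tfidf <- function(model, tokens_tbl) {
  stopifnot(inherits(model, "tfidf_model"))
  vocab <- model$vocabulary
  n_docs <- nrow(tokens_tbl)
  v <- nrow(vocab)
  idx <- purrr::map(tokens_tbl$tokens, function(tk) {
    m <- match(tk, vocab$token)
    m[!is.na(m)]
  })
  lens <- lengths(idx)
  i <- rep.int(seq_len(n_docs), lens)
  j <- unlist(idx, use.names = FALSE)
  X <- Matrix::sparseMatrix(i = i, j = j, x = rep(1, length(j)),
                            dims = c(n_docs, v),
                            dimnames = list(tokens_tbl$id, vocab$token))
  X <- methods::as(X, "CsparseMatrix")  # sums duplicates -> raw counts
  X <- X %*% Matrix::Diagonal(v, vocab$idf)
  if (model$normalize) {
    norms <- sqrt(Matrix::rowSums(X^2))
    zero <- norms == 0
    if (any(zero)) {
      message(sprintf("%d document(s) have no in-vocabulary tokens (zero row)",
                      sum(zero)))
    }
    norms[zero] <- 1
    X <- Matrix::Diagonal(n_docs, 1 / norms) %*% X
  }
  X <- methods::as(X, "CsparseMatrix")
  dimnames(X) <- list(tokens_tbl$id, vocab$token)
  X
}

#' Reduce a tf-idf matrix by truncated SVD (latent semantic analysis)
#'
#' Projects the document-term matrix onto its top `d` right singular
#' vectors, the LSA representation clustering operates in. The
#' decomposition is computed exactly by dense LAPACK SVD, which is fast at
#' the matrix sizes this package targets and removes any solver
#' stochasticity; each component's sign is fixed by making its
#' largest-magnitude entry positive.
#'
#' @param X Sparse or dense tf-idf matrix (docs x tokens).
#' @param d Target dimension, `1 <= d <= min(n_docs, n_tokens)`
#'   (the study-scale default is 300).
#' @param seed Ignored (accepted for interface compatibility; the exact
#'   solver is deterministic).
#' @return An object of class `lsa_model` with `d`, `components` (tokens x
#'   d orthonormal basis), `singular_values`, `captured_variance`, and
#'   `scores`, the reduced docs x d matrix.
#' @export
fit_lsa <- function(X, d = 300, seed = NULL) {
  n <- nrow(X)
  v <- ncol(X)
  if (d < 1 || d > min(n, v)) {
    stop_litthemes(
      sprintf("d = %d outside [1, min(n_docs = %d, vocab = %d)]", d, n, v),
      "litthemes_dimension_error")
  }
  dec <- svd(as.matrix(X))
  comps <- dec$v[, seq_len(d), drop = FALSE]
  # sign convention: largest-|entry| of each component positive
  flips <- vapply(seq_len(d), function(k) {
    col <- comps[, k]
    sign(col[which.max(abs(col))])
  }, numeric(1))
  flips[flips == 0] <- 1
  comps <- sweep(comps, 2, flips, `*`)
  rownames(comps) <- colnames(X)
  sv <- dec$d
  model <- structure(
    list(d = d, components = comps,
         singular_values = sv[seq_len(d)],
         captured_variance = sum(sv[seq_len(d)]^2) / sum(sv^2)),
    class = "lsa_model")
  model$scores <- transform_lsa(model, X)
  model
}

#' Project documents into a frozen LSA space
#'
#' @param model A fitted `lsa_model`.
#' @param X tf-idf matrix with the fit-time vocabulary as columns.
#' @return Dense docs x d matrix of reduced coordinates.
#' @export
transform_lsa <- function(model, X) {
  stopifnot(inherits(model, "lsa_model"))
  if (ncol(X) != nrow(model$components)) {
    stop_litthemes(
      sprintf("X has %d columns but the LSA basis expects %d",
              ncol(X), nrow(model$components)),
      "litthemes_dimension_error")
  }
  out <- as.matrix(X %*% model$components)
  rownames(out) <- rownames(X)
  out
}
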