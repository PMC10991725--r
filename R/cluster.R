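#' Number of greedy k-means++ candidates per seeding step
#'
#' The greedy variant draws `2 + floor(ln k)` candidate centroids at each
#' step and keeps the one that most reduces the clustering potential.
#'
#' @param k Number of clusters.
#' @return Integer candidate count.
#' @export
greedy_candidates <- function(k) {
  as.integer(2 + floor(log(k)))
}

#' Greedy k-means++ initial centroids
#'
#' Seeds k-means with the greedy k-means++ scheme: the first centroid is a
#' uniformly sampled row; each subsequent centroid is chosen among
#' `2 + floor(ln k)` candidates sampled with probability proportional to
#' the squared distance to the nearest already-chosen centroid, keeping the
#' candidate that minimises the resulting potential (sum of squared
#' nearest-centroid distances). Uses the R RNG, so `set.seed()` makes it
#' reproducible.
#'
#' @param X Numeric matrix, one row per document (reduced LSA space).
#' @param k Number of centroids, `k <= nrow(X)`.
#' @return A `k x ncol(X)` matrix of distinct rows of `X`.
#' @export
greedy_kmeanspp_init <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) {
    stop_litthemes(sprintf("k = %d exceeds the number of rows (%d)", k, n),
                   "litthemes_size_error")
  }
  if (k < 1) stop_litthemes("k must be >= 1", "litthemes_parameter_error")
  centers <- matrix(NA_real_, k, ncol(X))
  first <- sample.int(n, 1)
  centers[1, ] <- X[first, ]
  if (k == 1) return(centers)
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  n_cand <- greedy_candidates(k)
  for (c_idx in 2:k) {
    if (sum(d2) <= 0) {
      stop_litthemes(
        "fewer distinct rows than k; cannot seed distinct centroids",
        "litthemes_size_error")
    }
    cand <- sample.int(n, n_cand, replace = TRUE, prob = d2)
    pots <- vapply(cand, function(ci) {
      sum(pmin(d2, rowSums(sweep(X, 2, X[ci, ])^2)))
    }, numeric(1))
    best <- cand[which.min(pots)]
    centers[c_idx, ] <- X[best, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[best, ])^2))
  }
  centers
}

# Squared Euclidean distances between rows of X (n x d) and rows of C (k x d).
cross_dist2 <- function(X, C) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(C))) -
    2 * X %*% t(C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
  d2[d2 < 0] <- 0
  d2
}

#' Fit k-means on the reduced document matrix
#'
#' Lloyd iterations with greedy k-means++ initialisation: assign each
#' document to its nearest centroid by Euclidean distance (ties to the
#' lowest cluster id), recompute centroids as member means, and stop when
#' the assignments no longer change or `max_iter` is reached. An emptied
#' cluster is refilled with the point farthest from its own centroid, so
#' every cluster is non-empty by contract. The within-cluster sum of
#' squares (inertia) is recorded at every iteration and is non-increasing.
#'
#' @param X Numeric matrix of documents (rows) in reduced space.
#' @param k Number of clusters, `1 <= k <= nrow(X)`.
#' @param max_iter Maximum Lloyd iterations (default 300).
#' @param seed Optional RNG seed for the initialisation.
#' @param init Optional `k x d` matrix of initial centroids (overrides the
#'   seeded greedy k-means++ initialisation).
#' @return An object of class `theme_kmeans`: `k`, `centroids`,
#'   `assignments` (0-based cluster id per row), `inertia`,
#'   `inertia_trace`, `n_iter_run`, `converged`, `seed`.
#' @examples
#' X <- matrix(c(0, 1, 10, 11), ncol = 1)
#' fit <- kmeans_fit(X, k = 2, seed = 1)
#' fit$inertia
#' @export
kmeans_fit <- function(X, k, max_iter = 300, seed = NULL, init = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k <= 0) stop_litthemes("k must be positive", "litthemes_parameter_error")
  if (k > n) {
    stop_litthemes(sprintf("k = %d exceeds the number of rows (%d)", k, n),
                   "litthemes_size_error")
  }
  if (!is.null(seed)) set.seed(seed)
  centers <- if (is.null(init)) greedy_kmeanspp_init(X, k) else {
    stopifnot(nrow(init) == k, ncol(init) == ncol(X))
    as.matrix(init)
  }

  assign_step <- function(centers) {
    d2 <- cross_dist2(X, centers)
    cl <- max.col(-d2, ties.method = "first")
    list(cl = cl, inertia = sum(d2[cbind(seq_len(n), cl)]))
  }

  prev_cl <- rep(-1L, n)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  cl <- NULL
  for (iter in seq_len(max_iter)) {
    st <- assign_step(centers)
    cl <- st$cl
    # empty-cluster repair: refill with the point farthest from its centroid
    empties <- setdiff(seq_len(k), unique(cl))
    for (e in sort(empties)) {
      sizes <- tabulate(cl, nbins = k)
      movable <- which(sizes[cl] > 1)
      dist_own <- rowSums((X[movable, , drop = FALSE] -
                             centers[cl[movable], , drop = FALSE])^2)
      far <- movable[which.max(dist_own)]
      cl[far] <- e
      centers[e, ] <- X[far, ]
    }
    if (length(empties) > 0) {
      st <- list(cl = cl,
                 inertia = sum(cross_dist2(X, centers)[cbind(seq_len(n), cl)]))
    }
    trace <- c(trace, st$inertia)
    if (identical(cl, prev_cl)) {
      converged <- TRUE
      break
    }
    prev_cl <- cl
    for (c_idx in seq_len(k)) {
      members <- cl == c_idx
      centers[c_idx, ] <- colMeans(X[members, , drop = FALSE])
    }
  }
  final <- assign_step(centers)
  # a final non-converged reassignment could in principle empty a cluster
  empties <- setdiff(seq_len(k), unique(final$cl))
  for (e in sort(empties)) {
    sizes <- tabulate(final$cl, nbins = k)
    movable <- which(sizes[final$cl] > 1)
    dist_own <- rowSums((X[movable, , drop = FALSE] -
                           centers[final$cl[movable], , drop = FALSE])^2)
    far <- movable[which.max(dist_own)]
    final$cl[far] <- e
    centers[e, ] <- X[far, ]
  }
  if (length(empties) > 0) {
    final$inertia <- sum(cross_dist2(X, centers)[cbind(seq_len(n), final$cl)])
  }
  structure(
    list(k = k, centroids = centers, assignments = as.integer(final$cl - 1L),
         inertia = final$inertia, inertia_trace = trace,
         n_iter_run = iter, converged = converged, seed = seed),
    class = "theme_kmeans")
}

#' Silhouette coefficients for a clustering
#'
#' For each document `i`, `a(i)` is the mean Euclidean distance to the
#' other members of its cluster and `b(i)` the smallest mean distance to
#' the members of any other cluster; `s(i) = (b - a) / max(a, b)`, with
#' `s(i) = 0` for members of singleton clusters. The overall score (the
#' mean over documents) is the model-selection criterion for `k`.
#'
#' @param X Numeric document matrix (reduced space).
#' @param assignments 0-based cluster id per row.
#' @return An object of class `silhouette_result`: `per_doc` tibble
#'   (`doc`, `cluster`, `sil`), `per_cluster` tibble (`cluster`, `size`,
#'   `mean_sil`), and `overall`.
#' @export
silhouette_score <- function(X, assignments) {
  X <- as.matrix(X)
  n <- nrow(X)
  assignments <- validate_assignments(assignments, n)
  cl <- assignments + 1L
  k <- max(cl)
  sizes <- tabulate(cl, nbins = k)
  if (sum(sizes > 0) < 2) {
    stop_litthemes("silhouette is undefined for fewer than 2 clusters",
                   "litthemes_undefined_score_error")
  }
  D <- as.matrix(stats::dist(X))
  # S[i, c] = sum of distances from i to members of cluster c
  M <- matrix(0, n, k)
  M[cbind(seq_len(n), cl)] <- 1
  S <- D %*% M
  a <- ifelse(sizes[cl] > 1, S[cbind(seq_len(n), cl)] / (sizes[cl] - 1), 0)
  mean_other <- sweep(S, 2, pmax(sizes, 1), `/`)
  mean_other[cbind(seq_len(n), cl)] <- Inf
  mean_other[, sizes == 0] <- Inf
  b <- apply(mean_other, 1, min)
  s <- ifelse(sizes[cl] == 1, 0, (b - a) / pmax(a, b))
  s[is.nan(s)] <- 0  # a = b = 0: coincident points

  per_doc <- tibble(doc = seq_len(n), cluster = assignments, sil = s)
  per_cluster <- per_doc |>
    group_by(.data$cluster) |>
    summarise(size = n(), mean_sil = mean(.data$sil), .groups = "drop")
  structure(list(per_doc = per_doc, per_cluster = per_cluster,
                 overall = mean(s)),
            class = "silhouette_result")
}

#' Select the number of theme clusters by silhouette sweep
#'
#' Runs one seeded k-means fit per candidate `k` and scores it with the
#' overall silhouette coefficient; the best `k` is the argmax, ties broken
#' toward the smaller `k`. Per-`k` seeds are derived deterministically from
#' the global seed, so the whole sweep is reproducible. The study-scale
#' defaults sweep 50 to 500.
#'
#' @param X Numeric document matrix (reduced space).
#' @param k_min,k_max,step Sweep range (defaults 50, 500, 1).
#' @param max_iter Lloyd iteration cap per fit (default 300).
#' @param seed Global seed for the sweep.
#' @return An object of class `k_sweep`: `curve` tibble (`k`,
#'   `silhouette`), `best_k`, `best_score`, `best_model`.
#' @export
sweep_k <- function(X, k_min = 50, k_max = 500, step = 1, max_iter = 300,
                    seed = 1) {
  X <- as.matrix(X)
  if (k_max > nrow(X)) {
    stop_litthemes(
      sprintf("k_max = %d exceeds the number of documents (%d)",
              k_max, nrow(X)),
      "litthemes_parameter_error")
  }
  ks <- seq(k_min, k_max, by = step)
  ks <- ks[ks >= 2]
  if (length(ks) == 0) {
    stop_litthemes("empty k range (need k >= 2)", "litthemes_parameter_error")
  }
  scores <- vapply(ks, function(k) {
    fit <- kmeans_fit(X, k, max_iter = max_iter, seed = derive_seed(seed, k))
    silhouette_score(X, fit$assignments)$overall
  }, numeric(1))
  best_i <- which.max(scores)  # which.max takes the first maximum: smaller k
  best_k <- ks[best_i]
  best_model <- kmeans_fit(X, best_k, max_iter = max_iter,
                           seed = derive_seed(seed, best_k))
  structure(
    list(curve = tibble(k = ks, silhouette = scores),
         best_k = best_k, best_score = scores[best_i],
         best_model = best_model, seed = seed),
    class = "k_sweep")
}

#' Top centroid terms per cluster
#'
#' Describes each theme cluster by the tokens of highest mean tf-idf weight
#' over its members, computed in the original token space (not the reduced
#' space). Only word tokens are eligible; punctuation and number tokens are
#' excluded. Ties are broken lexicographically.
#'
#' @param assignments 0-based cluster id per document.
#' @param tfidf Sparse tf-idf matrix (docs x tokens) with token colnames.
#' @param n Number of terms per cluster (default 10).
#' @return Tibble with columns `cluster_id`, `rank`, `term`, `weight`.
#' @export
centroid_top_terms <- function(assignments, tfidf, n = 10) {
  assignments <- validate_assignments(assignments, nrow(tfidf))
  tokens <- colnames(tfidf)
  word <- is_word_token(tokens)
  clusters <- sort(unique(assignments))
  purrr::map_dfr(clusters, function(c_id) {
    members <- which(assignments == c_id)
    if (length(members) == 0) {
      stop_litthemes(sprintf("cluster %d has no members", c_id),
                     "litthemes_consistency_error")
    }
    mean_w <- Matrix::colMeans(tfidf[members, , drop = FALSE])[word]
    terms <- tokens[word]
    ord <- order(-mean_w, terms, method = "radix")
    top <- utils::head(ord, n)
    tibble(cluster_id = c_id, rank = seq_along(top),
           term = terms[top], weight = unname(mean_w[top]))
  })
}
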