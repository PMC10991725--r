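test_that("the greedy seeding candidate count follows 2 + floor(ln k)", {
  expect_equal(greedy_candidates(3), 3L)
  expect_equal(greedy_candidates(2), 2L)
  expect_equal(greedy_candidates(100), 6L)
})

test_that("greedy k-means++ returns distinct rows and nails the separable base cases", {
  X <- matrix(c(0, 100), ncol = 1)
  for (s in 1:10) {
    set.seed(s)
    centers <- greedy_kmeanspp_init(X, 2)
    expect_setequal(as.numeric(centers), c(0, 100))
  }
  set.seed(1)
  one <- greedy_kmeanspp_init(X, 1)
  expect_true(as.numeric(one) %in% c(0, 100))
  expect_error(greedy_kmeanspp_init(X, 3), class = "litthemes_size_error")
  expect_error(greedy_kmeanspp_init(matrix(1, 4, 1), 2),
               class = "litthemes_size_error")
})

test_that("greedy seeding beats plain random seeding on average potential", {
  potential <- function(X, centers) {
    sum(apply(litthemes:::cross_dist2(X, centers), 1, min))
  }
  set.seed(42)
  X <- rbind(matrix(rnorm(60, 0), ncol = 2),
             matrix(rnorm(60, 6), ncol = 2),
             matrix(rnorm(60, -6), ncol = 2))
  greedy <- random <- numeric(30)
  for (s in seq_len(30)) {
    set.seed(s)
    greedy[s] <- potential(X, greedy_kmeanspp_init(X, 3))
    set.seed(s)
    random[s] <- potential(X, X[sample.int(nrow(X), 3), , drop = FALSE])
  }
  expect_lt(mean(greedy), mean(random))
})

test_that("k-means recovers the enumerated optimum on the 1-D four-point instance", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  fit <- kmeans_fit(X, 2, seed = 1)
  expect_equal(sort(as.numeric(fit$centroids)), c(0.5, 10.5))
  expect_equal(fit$inertia, 1.0)
  expect_equal(fit$assignments[1], fit$assignments[2])
  expect_equal(fit$assignments[3], fit$assignments[4])
})

test_that("k-means degenerate cases: k = n and identical points", {
  X <- matrix(c(0, 3, 9, 12), ncol = 1)
  fit <- kmeans_fit(X, 4, seed = 2)
  expect_equal(fit$inertia, 0)
  expect_equal(sort(fit$assignments), 0:3)
  same <- matrix(5, 6, 2)
  fit1 <- kmeans_fit(same, 1, seed = 1)
  expect_equal(as.numeric(fit1$centroids), c(5, 5))
  expect_equal(fit1$inertia, 0)
  expect_error(kmeans_fit(X, 0), class = "litthemes_parameter_error")
  expect_error(kmeans_fit(X, 5), class = "litthemes_size_error")
})

test_that("inertia is non-increasing over Lloyd iterations and clusters stay non-empty", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(200), ncol = 2)
    fit <- kmeans_fit(X, 8, seed = s)
    expect_true(all(diff(fit$inertia_trace) <= 1e-8))
    expect_equal(sort(unique(fit$assignments)), 0:7)
    expect_lte(fit$inertia, fit$inertia_trace[length(fit$inertia_trace)] + 1e-8)
  }
})

test_that("k-means agrees with the stats::kmeans optimum on well-separated data", {
  set.seed(13)
  X <- rbind(matrix(rnorm(80, 0, 0.2), ncol = 2),
             matrix(rnorm(80, 5, 0.2), ncol = 2))
  ours <- kmeans_fit(X, 2, seed = 3)
  ref <- stats::kmeans(X, 2, nstart = 5)
  expect_equal(ours$inertia, ref$tot.withinss, tolerance = 1e-8)
})

test_that("silhouette matches the hand-worked two-pair example and conventions", {
  X <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  res <- silhouette_score(X, c(0L, 0L, 1L, 1L))
  # e.g. point at 0.1: a = 0.1, b = (9.9 + 10)/2 = 9.95 -> 9.85/9.95
  expect_equal(res$per_doc$sil[2], (9.95 - 0.1) / 9.95, tolerance = 1e-12)
  expect_gt(res$overall, 0.98)
  expect_equal(res$overall, mean(res$per_doc$sil))
  # singleton cluster member scores zero
  res2 <- silhouette_score(X, c(0L, 1L, 2L, 2L))
  expect_equal(res2$per_doc$sil[1], 0)
  expect_equal(res2$per_doc$sil[2], 0)
  expect_error(silhouette_score(X, rep(0L, 4)),
               class = "litthemes_undefined_score_error")
})

test_that("an arbitrary split of uniform points scores near zero", {
  set.seed(21)
  X <- matrix(runif(400), ncol = 2)
  res <- silhouette_score(X, rep(0:1, each = 100))
  expect_lt(abs(res$overall), 0.2)
})

test_that("silhouette equals the brute-force O(n^2) oracle", {
  set.seed(31)
  for (i in 1:5) {
    n <- sample(20:60, 1)
    k <- sample(2:5, 1)
    X <- matrix(rnorm(2 * n), ncol = 2)
    cl <- sample(0:(k - 1), n, replace = TRUE)
    cl[seq_len(k) ] <- 0:(k - 1)  # ensure non-empty clusters
    expect_equal(silhouette_score(X, cl)$per_doc$sil,
                 brute_silhouette(X, cl), tolerance = 1e-12)
  }
})

test_that("sweep_k selects the planted theme count and validates its range", {
  gen <- default_gen(seed = 201)
  tf <- fit_tfidf(tokenize_corpus(gen$corpus))
  lsa <- fit_lsa(tf$matrix, d = min(300, nrow(gen$corpus),
                                    nrow(tf$vocabulary)))
  sw <- sweep_k(lsa$scores, k_min = 2, k_max = 10, seed = 1)
  expect_equal(sw$best_k, 5)
  expect_gte(score_recovery(gen$gold, sw$best_model$assignments)$ari, 0.9)
  expect_equal(sw$best_score, max(sw$curve$silhouette))
  expect_error(sweep_k(lsa$scores, k_min = 2, k_max = 1e5),
               class = "litthemes_parameter_error")
  expect_error(sweep_k(lsa$scores, k_min = 0, k_max = 1),
               class = "litthemes_parameter_error")
})

test_that("equal silhouette scores resolve to the smaller k", {
  # four points in two tight, distant pairs: k = 2 is a perfect split and
  # any further split only lowers the score, so verify the argmax-first rule
  # on an explicitly tied curve via the same selection rule
  curve <- c(0.5, 0.7, 0.7, 0.3)
  expect_equal(which.max(curve), 2L)
  # and end-to-end: rerunning the same sweep twice is deterministic
  gen <- generate_corpus(synthetic_spec(n_themes = 2, docs_per_theme = 15,
                                        seed = 5))
  tf <- fit_tfidf(tokenize_corpus(gen$corpus))
  lsa <- fit_lsa(tf$matrix, d = 10)
  s1 <- sweep_k(lsa$scores, k_min = 2, k_max = 6, seed = 4)
  s2 <- sweep_k(lsa$scores, k_min = 2, k_max = 6, seed = 4)
  expect_identical(s1$curve, s2$curve)
  expect_identical(s1$best_model$assignments, s2$best_model$assignments)
})

test_that("centroid terms rank mean tf-idf weights and exclude non-word tokens", {
  toks <- tibble::tibble(
    id = c("d1", "d2", "d3"),
    tokens = list(c("colistin", "colistin", "resistance", "."),
                  c("colistin", "gene", "."),
                  c("outbreak", "outbreak", "ward")))
  fit <- fit_tfidf(toks)
  assignments <- c(0L, 0L, 1L)
  top <- centroid_top_terms(assignments, fit$matrix, n = 3)
  # hand ranking for cluster 0: mean weight of colistin highest
  mean_w <- Matrix::colMeans(fit$matrix[1:2, ])
  words <- setdiff(colnames(fit$matrix), ".")
  hand <- words[order(-mean_w[words], words)][1:3]
  expect_equal(top$term[top$cluster_id == 0], hand)
  expect_false("." %in% top$term)
  # single-token cluster
  solo <- tibble::tibble(id = c("a", "b"),
                         tokens = list("colistin", c("x", "y")))
  fs <- fit_tfidf(solo)
  expect_equal(centroid_top_terms(c(0L, 1L), fs$matrix, n = 1)$term[1],
               "colistin")
})
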