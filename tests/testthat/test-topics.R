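test_that("bag-of-features builds unigrams plus adjacency-respecting bigrams", {
  bow <- build_cluster_bow(list(c("colistin", "resistance")))
  expect_setequal(bow$features,
                  c("colistin", "resistance", "colistin_resistance"))
  bow2 <- build_cluster_bow(list(c("colistin", ".", "resistance")))
  expect_setequal(bow2$features, c("colistin", "resistance"))
  # two docs sharing no tokens: every doc frequency is 1
  bow3 <- build_cluster_bow(list(c("a1", "b1"), c("c1", "d1")))
  expect_true(all(bow3$doc_freq == 1))
  expect_error(build_cluster_bow(list()), class = "litthemes_parameter_error")
})

test_that("bigrams are ordered and counted with multiplicity", {
  bow <- build_cluster_bow(list(c("a1", "b1", "a1", "b1")))
  expect_true("a1_b1" %in% bow$features)
  expect_true("b1_a1" %in% bow$features)
  expect_equal(as.numeric(bow$counts[1, "a1_b1"]), 2)
  expect_equal(as.numeric(bow$counts[1, "b1_a1"]), 1)
})

test_that("single-topic LDA reduces to the smoothed corpus frequencies", {
  bow <- build_cluster_bow(list(c("a1", "a1", "b1"), c("a1", "c1")))
  cfg <- topic_config(gibbs_iters = 5, seed = 1)
  m <- lda_gibbs(bow, 1, cfg)
  counts <- Matrix::colSums(bow$counts)
  f <- length(bow$features)
  expect_equal(as.numeric(m$topic_word[1, names(counts)]),
               as.numeric((counts + cfg$beta) / (sum(counts) + f * cfg$beta)),
               tolerance = 1e-12)
  expect_equal(as.numeric(m$doc_topic), c(1, 1), tolerance = 1e-12)
})

test_that("LDA point estimates are proper distributions and runs are bit-reproducible", {
  set.seed(77)
  docs <- lapply(1:20, function(i) sample(sprintf("w%02d", 1:15), 25, TRUE))
  bow <- build_cluster_bow(docs)
  cfg <- topic_config(gibbs_iters = 50, seed = 99)
  m1 <- lda_gibbs(bow, 3, cfg)
  m2 <- lda_gibbs(bow, 3, cfg)
  expect_identical(m1$assignments, m2$assignments)
  expect_identical(m1$topic_word, m2$topic_word)
  expect_equal(unname(rowSums(m1$topic_word)), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(rowSums(m1$doc_topic)), rep(1, 20), tolerance = 1e-9)
  expect_warning(lda_gibbs(build_cluster_bow(list(c("a1", "b1"))), 5,
                           topic_config(gibbs_iters = 2, seed = 1)),
                 "exceeds")
})

test_that("Gibbs bookkeeping conserves per-word counts at every iteration", {
  set.seed(7)
  docs <- lapply(1:10, function(i) sample(sprintf("w%02d", 1:8), 15, TRUE))
  bow <- build_cluster_bow(docs)
  m <- lda_gibbs(bow, 3, topic_config(gibbs_iters = 30, seed = 2),
                 check_counts = TRUE)  # sampler aborts on any drift
  word_totals <- Matrix::colSums(bow$counts)
  est_totals <- tabulate(m$assignments + 1L, nbins = 3)
  expect_equal(sum(est_totals), sum(word_totals))
})

test_that("LDA recovers two planted disjoint vocabularies in >= 9 of 10 seeds", {
  ok <- vapply(1:10, function(s) {
    set.seed(s)
    vocab_a <- sprintf("aa%02d", 1:10)
    vocab_b <- sprintf("bb%02d", 1:10)
    docs <- c(lapply(1:50, function(i) sample(vocab_a, 30, TRUE)),
              lapply(1:50, function(i) sample(vocab_b, 30, TRUE)))
    bow <- build_cluster_bow(docs)
    m <- lda_gibbs(bow, 2, topic_config(gibbs_iters = 300, seed = 1000 + s))
    tops <- lapply(1:2, function(t) {
      p <- m$topic_word[t, ]
      names(sort(p, decreasing = TRUE))[1:5]
    })
    pure <- function(x) all(startsWith(x, "aa")) || all(startsWith(x, "bb"))
    pure(tops[[1]]) && pure(tops[[2]]) &&
      !identical(startsWith(tops[[1]][1], "aa"),
                 startsWith(tops[[2]][1], "aa"))
  }, logical(1))
  expect_gte(sum(ok), 9)
})

test_that("UMass coherence evaluates the closed-form pair examples", {
  # two words always co-occurring in 5 docs
  docs_always <- lapply(1:5, function(i) c("u1", "u2"))
  bow_a <- build_cluster_bow(docs_always)
  expect_equal(umass_coherence(c("u1", "u2"), bow_a, epsilon = 1),
               log(6 / 5), tolerance = 1e-12)
  # never co-occurring; the conditioning word appears in 5 documents
  docs_never <- c(lapply(1:5, function(i) c("u1", "x9")),
                  lapply(1:3, function(i) c("u2", "y9")))
  bow_n <- build_cluster_bow(docs_never)
  expect_equal(umass_coherence(c("u1", "u2"), bow_n, epsilon = 1),
               log(1 / 5), tolerance = 1e-12)
  expect_equal(umass_coherence("u1", bow_n), 0)
  expect_error(umass_coherence(c("u1", "zz"), bow_n),
               class = "litthemes_contract_error")
})

test_that("UMass coherence equals the brute-force pair-enumeration oracle", {
  set.seed(17)
  docs <- lapply(1:30, function(i) unique(sample(sprintf("w%02d", 1:25),
                                                 sample(5:15, 1))))
  bow <- build_cluster_bow(docs)
  for (m_words in c(2, 5, 12, 20)) {
    words <- sample(bow$features[grepl("^w\\d+$", bow$features)], m_words)
    expect_equal(umass_coherence(words, bow, epsilon = 1),
                 brute_umass(words, docs, epsilon = 1), tolerance = 1e-12)
  }
})

test_that("the topic sweep averages over clusters and takes the most negative T", {
  set.seed(3)
  docs1 <- lapply(1:8, function(i) sample(sprintf("p%02d", 1:10), 12, TRUE))
  docs2 <- lapply(1:8, function(i) sample(sprintf("q%02d", 1:10), 12, TRUE))
  bows <- list(`0` = build_cluster_bow(docs1), `1` = build_cluster_bow(docs2))
  sw <- sweep_topics(bows, t_min = 1, t_max = 3,
                     config = topic_config(gibbs_iters = 40, seed = 5))
  expect_equal(nrow(sw$curve), 3)
  expect_equal(sw$curve$mean_coherence[sw$curve$n_topics == sw$selected_t],
               min(sw$curve$mean_coherence))
  # curve is the unweighted mean of the per-cluster values
  manual <- tapply(sw$per_cluster$coherence, sw$per_cluster$n_topics, mean)
  expect_equal(sw$curve$mean_coherence, as.numeric(manual), tolerance = 1e-12)
  # the final models all share the selected T
  expect_true(all(vapply(sw$models, function(m) m$n_topics,
                         numeric(1)) == sw$selected_t))
})

test_that("clusters with a single coherent sub-vocabulary select one topic", {
  selected <- vapply(1:5, function(s) {
    gen <- generate_corpus(synthetic_spec(
      n_themes = 3, docs_per_theme = 15, signature_vocab_size = 40,
      signature_weight = 0.95, abstract_len_range = c(400, 500),
      seed = 100 + s))
    toks <- tokenize_corpus(gen$corpus)
    bows <- lapply(1:3, function(t)
      build_cluster_bow(toks$tokens[gen$gold$theme == t]))
    sweep_topics(bows, t_min = 1, t_max = 3,
                 config = topic_config(gibbs_iters = 150, seed = s))$selected_t
  }, numeric(1))
  expect_true(all(selected == 1))
})

test_that("representative terms concatenate topics in order and de-duplicate", {
  bow <- build_cluster_bow(list(c("a1", "b1", "c1", "d1")))
  m <- lda_gibbs(bow, 1, topic_config(gibbs_iters = 5, seed = 1))
  expect_length(representative_terms(m, per_topic = 2), 2)
  # fabricated model with a term shared across topics
  fake <- structure(list(
    n_topics = 2,
    topic_word = matrix(c(0.5, 0.3, 0.1, 0.1,
                          0.1, 0.5, 0.3, 0.1), 2, 4, byrow = TRUE,
                        dimnames = list(NULL, c("x1", "y1", "z1", "w1"))),
    features = c("x1", "y1", "z1", "w1")), class = "lda_model")
  expect_equal(representative_terms(fake, per_topic = 2),
               c("x1", "y1", "z1"))
})
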