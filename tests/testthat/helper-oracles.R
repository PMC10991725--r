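# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles deliberately use naive O(n^2) / pair-enumeration
# formulations so they stay independent of the package's optimised paths.

# Brute-force silhouette: direct double loop over the definition.
brute_silhouette <- function(X, assignments) {
  X <- as.matrix(X)
  n <- nrow(X)
  cl <- assignments
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i])
    if (length(own) == 1) {
      s[i] <- 0
      next
    }
    a <- mean(vapply(setdiff(own, i), function(j)
      sqrt(sum((X[i, ] - X[j, ])^2)), numeric(1)))
    b <- Inf
    for (c2 in setdiff(unique(cl), cl[i])) {
      members <- which(cl == c2)
      d <- mean(vapply(members, function(j)
        sqrt(sum((X[i, ] - X[j, ])^2)), numeric(1)))
      b <- min(b, d)
    }
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# Brute-force UMass coherence: explicit pair enumeration over raw document
# feature sets.
brute_umass <- function(top_words, doc_feature_sets, epsilon = 1) {
  m <- length(top_words)
  if (m < 2) return(0)
  d_one <- function(w) sum(vapply(doc_feature_sets, function(s) w %in% s,
                                  logical(1)))
  d_two <- function(w1, w2) sum(vapply(doc_feature_sets, function(s)
    (w1 %in% s) && (w2 %in% s), logical(1)))
  total <- 0
  for (i in 2:m) {
    for (j in seq_len(i - 1)) {
      total <- total +
        log((d_two(top_words[i], top_words[j]) + epsilon) /
              d_one(top_words[j]))
    }
  }
  total
}

# A tiny hand-written corpus tibble.
toy_corpus <- function() {
  tibble::tibble(
    id = c("p1", "p2", "p3", "p4", "p5"),
    title = c("Colistin resistance in clinical isolates",
              "Carbapenem resistance genes",
              "Colistin and polymyxin therapy",
              "Hospital outbreak surveillance",
              "Carbapenemase producing strains"),
    abstract = c("We study colistin resistance mechanisms.",
                 "Genes conferring carbapenem resistance were found.",
                 "",
                 "An outbreak in the hospital was tracked.",
                 "Strains producing carbapenemase spread."),
    year = c(2019L, 2020L, 2021L, 2018L, 2020L),
    date = NA_character_,
    journal = c("J One", "J Two", "J One", "J Three", "J Two")
  )
}

# Default synthetic study conditions used by several tests.
default_gen <- function(seed = 11) {
  generate_corpus(synthetic_spec(seed = seed))
}
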