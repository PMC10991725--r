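Package: litthemes
Title: Theme Discovery and Research-Trend Analysis for Bibliographic Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An unsupervised pipeline for mapping the research themes of a
    scientific literature corpus from titles and abstracts. Publications are
    tokenized and lemmatized, embedded as L2-normalised tf-idf vectors,
    projected to a low-dimensional latent semantic space by truncated SVD,
    and partitioned with k-means (greedy k-means++ seeding) with the number
    of clusters selected by the mean silhouette coefficient. Each theme
    cluster is described by centroid terms and by representative terms from
    per-cluster latent Dirichlet allocation fitted over lemma unigrams and
    ordered lemma pairs, with the shared topic number selected by UMass
    coherence. Downstream tools chart publications per theme per year,
    audit keywords across clusters, evaluate manual labels against the
    automatic terms, and assign new publications to the frozen model by
    nearest centroid. A synthetic-corpus generator with planted theme
    vocabularies, Zipfian background text and per-theme year windows makes
    every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    mclust,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
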