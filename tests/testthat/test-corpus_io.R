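test_that("TSV corpora are read in file order with contract handling of empties", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    id = c("p1", "p2", "p3"),
    title = c("T one", "T two", "T three"),
    abstract = c("A one", "", "A three"),
    year = c(2019L, 2020L, 2021L)
  ), tf)
  corpus <- read_corpus(tf, "tsv")
  expect_equal(corpus$id, c("p1", "p2", "p3"))
  expect_equal(corpus$abstract[2], "")
  expect_equal(corpus$journal, rep("", 3))
})

test_that("records with empty titles or unparseable years are dropped with warnings", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    id = c("p1", "p2", "p3"),
    title = c("Kept", "", "Also kept"),
    abstract = c("a", "b", "c"),
    year = c("2019", "2020", "twenty")
  ), tf)
  expect_warning(expect_warning(corpus <- read_corpus(tf, "tsv"),
                                "empty title"),
                 "unparseable year")
  expect_equal(corpus$id, "p1")
})

test_that("a missing mandatory column is a format error naming the column", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(id = "p1", title = "T", year = 2020L), tf)
  expect_error(read_corpus(tf, "tsv"), "abstract",
               class = "litthemes_format_error")
  expect_error(read_corpus(file.path(tempdir(), "no-such-file.tsv"), "tsv"),
               class = "litthemes_io_error")
})

test_that("write/read round trips preserve all fields in all three formats", {
  corpus <- toy_corpus()
  corpus$date <- c("2019-05-01", NA, "2021-02-03", NA, "2020-11-30")
  for (fmt in c("tsv", "jsonl", "medline")) {
    tf <- withr::local_tempfile()
    write_corpus(corpus, tf, fmt)
    back <- read_corpus(tf, fmt)
    expect_equal(back$id, corpus$id, info = fmt)
    expect_equal(back$title, corpus$title, info = fmt)
    expect_equal(back$abstract, corpus$abstract, info = fmt)
    expect_equal(back$year, corpus$year, info = fmt)
    expect_equal(back$journal, corpus$journal, info = fmt)
  }
})

test_that("MEDLINE tag mapping and continuation-line joining follow the dialect", {
  tf <- withr::local_tempfile()
  writeLines(c(
    "PMID- 12345",
    "TI  - A long title that",
    "      continues on the next line",
    "AB  - The abstract.",
    "DP  - 2020 Jan 15",
    "TA  - J Clin Microbiol",
    "",
    "PMID- 67890",
    "TI  - Second title",
    "DP  - 1999"
  ), tf)
  corpus <- read_corpus(tf, "medline")
  expect_equal(corpus$id, c("12345", "67890"))
  expect_equal(corpus$title[1], "A long title that continues on the next line")
  expect_equal(corpus$abstract, c("The abstract.", ""))
  expect_equal(corpus$year, c(2020L, 1999L))
  expect_equal(corpus$journal[1], "J Clin Microbiol")
})

test_that("the clustering table has one row per publication with its cluster's terms", {
  corpus <- toy_corpus()
  assignments <- c(0L, 1L, 0L, 1L, 1L)
  desc <- build_descriptions(
    corpus, assignments,
    lda_terms = list(`0` = c("colistin", "polymyxin"),
                     `1` = c("carbapenem", "outbreak")),
    centroid_terms = list(`0` = c("colistin", "resistance"),
                          `1` = c("resistance", "gene")))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_clustering_table(corpus, assignments, desc, tf)
  back <- readr::read_tsv(tf, show_col_types = FALSE)
  expect_equal(nrow(back), 5)
  expect_equal(back$cluster, assignments)
  expect_equal(back$lda_terms[1], "colistin polymyxin")
  expect_equal(back$lda_terms[2], "carbapenem outbreak")
  # record without a description for its cluster
  expect_error(write_clustering_table(corpus, c(0L, 1L, 0L, 1L, 2L), desc, tf),
               class = "litthemes_consistency_error")
  # empty corpus -> header-only file
  write_clustering_table(corpus[0, ], integer(0), desc, tf)
  expect_equal(nrow(readr::read_tsv(tf, show_col_types = FALSE)), 0)
})

test_that("terms containing the delimiter survive the quoting round trip", {
  corpus <- toy_corpus()[1, ]
  desc <- build_descriptions(corpus, 0L,
                             lda_terms = list(`0` = c("has\ttab", "plain")),
                             centroid_terms = list(`0` = "plain"))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_clustering_table(corpus, 0L, desc, tf)
  back <- readr::read_tsv(tf, show_col_types = FALSE)
  expect_equal(back$lda_terms, "has\ttab plain")
})

test_that("the labelling table is sorted, keeps empty labels, and spans member years", {
  corpus <- toy_corpus()
  assignments <- c(2L, 0L, 2L, 1L, 0L)
  desc <- build_descriptions(corpus, assignments,
                             lda_terms = list(), centroid_terms = list())
  desc <- desc[c(3, 1, 2), ]  # shuffle; writer must re-sort
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_labelling_table(desc, tf)
  back <- readr::read_tsv(tf, show_col_types = FALSE)
  expect_equal(back$cluster_id, c(0L, 1L, 2L))
  expect_true(all(is.na(back$label)))
  # start/end years = min/max of member years, checked against assignments
  expect_equal(back$start_year[back$cluster_id == 0], 2020L)
  expect_equal(back$end_year[back$cluster_id == 0], 2020L)
  expect_equal(back$start_year[back$cluster_id == 2], 2019L)
  expect_equal(back$end_year[back$cluster_id == 2], 2021L)
  dup <- dplyr::bind_rows(desc, desc[1, ])
  expect_error(write_labelling_table(dup, tf),
               class = "litthemes_consistency_error")
})

test_that("reference cluster rows (sizes and year spans) are representable without loss", {
  # shapes like the published sample rows: a 14-publication 2012-2022
  # cluster and a 110-publication 1998-2022 cluster
  desc <- tibble::tibble(
    cluster_id = c(15L, 63L), size = c(14L, 110L),
    label = c("Polymyxin and metabolic studies", NA),
    start_year = c(2012L, 1998L), end_year = c(2022L, 2022L),
    lda_terms = list(c("metabolic", "difference"),
                     c("growth", "protein")),
    centroid_terms = list(c("polymyxin", "combination"),
                          c("resistance", "antimicrobial")))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_labelling_table(desc, tf)
  back <- readr::read_tsv(tf, show_col_types = FALSE)
  expect_equal(back$size, c(14L, 110L))
  expect_equal(back$start_year, c(2012L, 1998L))
  expect_equal(back$end_year, c(2022L, 2022L))
  expect_equal(back$centroid_terms[2], "resistance antimicrobial")
})
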