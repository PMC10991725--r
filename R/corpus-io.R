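#' Read a bibliographic corpus
#'
#' Reads publication records (id, title, abstract, publication year, and
#' optionally date and journal) from a delimited table, JSON-lines, or
#' MEDLINE-format flat text, and returns them as a tibble in file order.
#'
#' Records with an empty title are dropped with a warning (a title is the
#' minimum text the pipeline needs); an empty abstract is retained as `""`.
#' A year field that is present but unparseable drops the record with a
#' warning; an absent year is kept as `NA` (such records are clustered but
#' excluded from trend series).
#'
#' The MEDLINE dialect maps `PMID`->id, `TI`->title, `AB`->abstract,
#' `TA`->journal and takes the year as the first four-digit token of `DP`;
#' continuation lines are joined with a single space.
#'
#' @param path Path to the input file.
#' @param format One of `"tsv"`, `"csv"`, `"jsonl"`, `"medline"`.
#' @return A tibble with columns `id`, `title`, `abstract`, `year`, `date`,
#'   `journal`, carrying the source path as a `"provenance"` attribute.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' readr::write_tsv(tibble::tibble(
#'   id = c("p1", "p2"), title = c("A study", "Another"),
#'   abstract = c("We show X.", ""), year = c(2020L, 2021L)
#' ), tf)
#' read_corpus(tf, "tsv")
#' @export
read_corpus <- function(path, format = c("tsv", "csv", "jsonl", "medline")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_litthemes(sprintf("cannot read corpus file '%s'", path),
                   "litthemes_io_error")
  }
  raw <- switch(format,
    tsv = readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          comment = "#", progress = FALSE),
    csv = readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          comment = "#", progress = FALSE),
    jsonl = read_jsonl_records(path),
    medline = read_medline_records(path)
  )
  if (format %in% c("tsv", "csv", "jsonl")) {
    missing_cols <- setdiff(c("id", "title", "abstract", "year"), names(raw))
    if (length(missing_cols) > 0) {
      stop_litthemes(
        sprintf("corpus file '%s' is missing column(s): %s", path,
                paste(missing_cols, collapse = ", ")),
        "litthemes_format_error"
      )
    }
  }
  corpus <- normalise_corpus_columns(raw)

  no_title <- is.na(corpus$title) | corpus$title == ""
  if (any(no_title)) {
    warn(sprintf("dropping %d record(s) with empty title: %s",
                 sum(no_title),
                 paste(utils::head(corpus$id[no_title], 5), collapse = ", ")))
    corpus <- corpus[!no_title, ]
  }
  bad_year <- !is.na(corpus$.year_raw) & corpus$.year_raw != "" &
    is.na(corpus$year)
  if (any(bad_year)) {
    warn(sprintf("dropping %d record(s) with unparseable year: %s",
                 sum(bad_year),
                 paste(utils::head(corpus$id[bad_year], 5), collapse = ", ")))
    corpus <- corpus[!bad_year, ]
  }
  corpus$.year_raw <- NULL
  validate_corpus(corpus)
  attr(corpus, "provenance") <- sprintf("%s file %s", format, path)
  corpus
}

normalise_corpus_columns <- function(raw) {
  out <- tibble(
    id = as.character(raw$id),
    title = as.character(raw$title %||% ""),
    abstract = as.character(raw$abstract %||% ""),
    .year_raw = as.character(raw$year %||% NA_character_),
    date = as.character(if ("date" %in% names(raw)) raw$date else NA_character_),
    journal = as.character(if ("journal" %in% names(raw)) raw$journal else "")
  )
  out$abstract[is.na(out$abstract)] <- ""
  out$journal[is.na(out$journal)] <- ""
  out$year <- suppressWarnings(as.integer(out$.year_raw))
  out
}

read_jsonl_records <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- purrr::map(lines, function(l) {
    obj <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    tibble(
      id = as.character(obj$id %||% NA_character_),
      title = as.character(obj$title %||% NA_character_),
      abstract = as.character(obj$abstract %||% ""),
      year = as.character(obj$year %||% NA_character_),
      date = as.character(obj$date %||% NA_character_),
      journal = as.character(obj$journal %||% "")
    )
  })
  out <- bind_rows(recs)
  if (nrow(out) == 0) {
    out <- tibble(id = character(), title = character(),
                  abstract = character(), year = character(),
                  date = character(), journal = character())
  }
  out
}

# MEDLINE flat text: records separated by blank lines; a field line is
# "TAG - value" with the tag padded to four characters; continuation lines
# start with whitespace and are joined with a single space.
read_medline_records <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  rec_breaks <- cumsum(!nzchar(trimws(lines)))
  groups <- split(lines, rec_breaks)
  recs <- purrr::map(groups, function(g) {
    g <- g[nzchar(trimws(g))]
    if (length(g) == 0) return(NULL)
    tags <- character(0)
    values <- character(0)
    for (line in g) {
      if (grepl("^\\s", line)) {
        if (length(values) > 0) {
          values[length(values)] <- paste(values[length(values)],
                                          trimws(line))
        }
      } else {
        tags <- c(tags, trimws(substr(line, 1, 4)))
        values <- c(values, trimws(sub("^.{4}-\\s?", "", line)))
      }
    }
    field <- function(tag) {
      i <- which(tags == tag)
      if (length(i) == 0) NA_character_ else values[i[1]]
    }
    dp <- field("DP")
    year <- if (is.na(dp)) NA_character_ else
      stringr::str_extract(dp, "\\b\\d{4}\\b")
    tibble(
      id = field("PMID"), title = field("TI"),
      abstract = field("AB") %||% NA_character_,
      year = year, date = dp, journal = field("TA")
    )
  })
  out <- bind_rows(recs)
  out$abstract[is.na(out$abstract)] <- ""
  out
}

#' Write a corpus back to disk
#'
#' Inverse of [read_corpus()]: the written file reads back to an identical
#' record list (byte-for-byte field round trip) for all three formats.
#'
#' @param corpus A corpus tibble as returned by [read_corpus()].
#' @param path Output path.
#' @param format One of `"tsv"`, `"jsonl"`, `"medline"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("tsv", "jsonl", "medline")) {
  format <- match.arg(format)
  validate_corpus(corpus)
  switch(format,
    tsv = readr::write_tsv(
      corpus[, c("id", "title", "abstract", "year", "date", "journal")], path),
    jsonl = {
      lines <- purrr::pmap_chr(
        corpus[, c("id", "title", "abstract", "year", "date", "journal")],
        function(id, title, abstract, year, date, journal) {
          jsonlite::toJSON(
            list(id = id, title = title, abstract = abstract,
                 year = year, date = date, journal = journal),
            auto_unbox = TRUE, null = "null", na = "null")
        })
      readr::write_lines(lines, path)
    },
    medline = {
      blocks <- purrr::pmap_chr(
        corpus[, c("id", "title", "abstract", "year", "date", "journal")],
        function(id, title, abstract, year, date, journal) {
          dp <- if (!is.na(date) && nzchar(date)) date else
            if (!is.na(year)) as.character(year) else ""
          fields <- c(
            sprintf("PMID- %s", id),
            sprintf("TI  - %s", title),
            if (nzchar(abstract)) sprintf("AB  - %s", abstract),
            if (nzchar(dp)) sprintf("DP  - %s", dp),
            if (nzchar(journal)) sprintf("TA  - %s", journal)
          )
          paste(fields, collapse = "\n")
        })
      readr::write_lines(paste(blocks, collapse = "\n\n"), path)
    }
  )
  invisible(path)
}

#' Write the per-publication clustering table
#'
#' One row per publication carrying its title, abstract, date, journal,
#' cluster id, and the cluster's LDA and centroid term lists — the layout of
#' the supplementary clustering table that supports manual interpretation.
#'
#' @param corpus Corpus tibble.
#' @param assignments Integer cluster id (0-based) per record, in corpus order.
#' @param descriptions Cluster descriptions from [build_descriptions()].
#' @param path Output TSV path.
#' @param config_hash Optional hash string written as a leading comment line.
#' @return `path`, invisibly.
#' @export
write_clustering_table <- function(corpus, assignments, descriptions, path,
                                   config_hash = NULL) {
  validate_corpus(corpus)
  assignments <- validate_assignments(assignments, nrow(corpus))
  missing_desc <- setdiff(unique(assignments), descriptions$cluster_id)
  if (length(missing_desc) > 0) {
    stop_litthemes(
      sprintf("no description for assigned cluster(s): %s",
              paste(sort(missing_desc), collapse = ", ")),
      "litthemes_consistency_error"
    )
  }
  desc <- tibble(
    cluster = descriptions$cluster_id,
    lda_terms = purrr::map_chr(descriptions$lda_terms, paste, collapse = " "),
    centroid_terms = purrr::map_chr(descriptions$centroid_terms, paste,
                                    collapse = " ")
  )
  out <- corpus |>
    mutate(cluster = assignments) |>
    select("id", "title", "abstract", "date", "journal", "cluster") |>
    left_join(desc, by = "cluster")
  write_table_with_hash(out, path, config_hash)
}

#' Write the cluster labelling table
#'
#' One row per theme cluster: id, size, manual label (empty until curated),
#' start and end year, and the automatic LDA / centroid term lists, sorted
#' by cluster id.
#'
#' @param descriptions Cluster descriptions from [build_descriptions()].
#' @param path Output TSV path.
#' @param config_hash Optional hash string written as a leading comment line.
#' @return `path`, invisibly.
#' @export
write_labelling_table <- function(descriptions, path, config_hash = NULL) {
  if (nrow(descriptions) == 0) {
    stop_litthemes("descriptions must be non-empty", "litthemes_parameter_error")
  }
  if (anyDuplicated(descriptions$cluster_id)) {
    stop_litthemes("duplicate cluster ids in descriptions",
                   "litthemes_consistency_error")
  }
  out <- descriptions |>
    arrange(.data$cluster_id) |>
    mutate(
      label = ifelse(is.na(.data$label), "", .data$label),
      lda_terms = purrr::map_chr(.data$lda_terms, paste, collapse = " "),
      centroid_terms = purrr::map_chr(.data$centroid_terms, paste,
                                      collapse = " ")
    ) |>
    select("cluster_id", "size", "label", "start_year", "end_year",
           "lda_terms", "centroid_terms")
  write_table_with_hash(out, path, config_hash)
}

write_table_with_hash <- function(tbl, path, config_hash = NULL) {
  if (!is.null(config_hash)) {
    readr::write_lines(sprintf("# config_hash: %s", config_hash), path)
    readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE, quote = "needed", escape = "double")
  } else {
    readr::write_tsv(tbl, path, quote = "needed", escape = "double")
  }
  invisible(path)
}
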