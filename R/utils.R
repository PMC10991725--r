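# Shared internal helpers.

# A token counts as a "word" token if it contains at least one letter;
# pure numbers, punctuation and symbols are non-word tokens.
is_word_token <- function(tokens) {
  stringr::str_detect(tokens, "\\p{L}")
}

# Deterministic per-task seed derived from a global seed and an index,
# kept strictly inside the 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647)
}

stop_litthemes <- function(msg, class) {
  abort(msg, class = c(class, "litthemes_error"))
}

# Validate a corpus tibble: id/title mandatory and well formed, year within
# a sane publication range (NA allowed: such records are kept for clustering
# but excluded from trend analysis).
validate_corpus <- function(corpus, arg = "corpus") {
  required <- c("id", "title", "abstract", "year")
  missing_cols <- setdiff(required, names(corpus))
  if (length(missing_cols) > 0) {
    stop_litthemes(
      sprintf("%s is missing mandatory column(s): %s", arg,
              paste(missing_cols, collapse = ", ")),
      "litthemes_format_error"
    )
  }
  if (anyDuplicated(corpus$id)) {
    stop_litthemes(sprintf("%s has duplicate record ids", arg),
                   "litthemes_consistency_error")
  }
  if (any(!is.na(corpus$id) & corpus$id == "") || anyNA(corpus$id)) {
    stop_litthemes(sprintf("%s has empty record ids", arg),
                   "litthemes_consistency_error")
  }
  bad_year <- !is.na(corpus$year) & (corpus$year < 1800 | corpus$year > 2100)
  if (any(bad_year)) {
    stop_litthemes(
      sprintf("%s has publication years outside [1800, 2100]: %s", arg,
              paste(utils::head(corpus$id[bad_year], 5), collapse = ", ")),
      "litthemes_consistency_error"
    )
  }
  invisible(corpus)
}

# Assignments are 0-based cluster ids aligned with corpus rows.
validate_assignments <- function(assignments, n_docs) {
  if (length(assignments) != n_docs || anyNA(assignments)) {
    stop_litthemes("every record must carry a cluster assignment",
                   "litthemes_consistency_error")
  }
  invisible(as.integer(assignments))
}
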