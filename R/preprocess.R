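#' Assemble the analysis document for one publication
#'
#' Concatenates title and abstract into the single text the pipeline
#' vectorizes. A terminal period is appended to the title if it does not
#' already end in sentence-final punctuation, so the title reads as its own
#' sentence; an empty abstract leaves the title unchanged.
#'
#' @param title Publication title (non-empty).
#' @param abstract Abstract text, possibly `""`.
#' @return A single string.
#' @examples
#' assemble_document("A study", "We show X.")
#' @export
assemble_document <- function(title, abstract = "") {
  if (length(title) != 1 || is.na(title) || !nzchar(title)) {
    stop_litthemes("title must be a non-empty string",
                   "litthemes_parameter_error")
  }
  abstract <- if (length(abstract) == 0 || is.na(abstract)) "" else abstract
  if (!nzchar(abstract)) {
    return(title)
  }
  sep_title <- if (stringr::str_detect(title, "[.!?]$")) title else
    paste0(title, ".")
  paste(sep_title, abstract)
}

#' Tokenize text into words, numbers, punctuation and symbols
#'
#' Splits a text so that every non-whitespace character belongs to exactly
#' one token, in input order. Runs of unicode word characters joined by
#' internal hyphens or underscores form a single token (so gene names such
#' as `blaOXA-23` survive intact); every other non-space character is a
#' single-character token.
#'
#' @param text A character string (may be `""`).
#' @return Character vector of tokens (length 0 for empty input).
#' @examples
#' tokenize("blaOXA-23 genes.")
#' @export
tokenize <- function(text) {
  if (length(text) != 1 || is.na(text)) {
    stop_litthemes("text must be a single string", "litthemes_parameter_error")
  }
  if (!nzchar(text)) return(character(0))
  pattern <- "[\\p{L}\\p{N}_]+(?:-[\\p{L}\\p{N}_]+)*|\\S"
  stringr::str_extract_all(text, pattern)[[1]]
}

#' Built-in rule-based English lemmatizer
#'
#' A deterministic, dependency-free lemmatizer plugin: an irregular-form
#' lookup table plus suffix rules (`-ies` to `-y`, `-ied` to `-y`, plural
#' `-es`/`-s` stripping with an exception list, `-ing`/`-ed` stripping with
#' a final-consonant undoubling heuristic). It maps inflected verbs toward
#' a base form and plural nouns to the singular (studying/studied/studies
#' to study; strains to strain), is the identity on punctuation, number and
#' symbol tokens, and lowercases word tokens. Intended as the reproducible
#' default; a neural lemmatizer can be supplied through the same plugin
#' contract via [lemmatizer_plugin()].
#'
#' @return A lemmatizer plugin (see [lemmatizer_plugin()]).
#' @examples
#' lem <- builtin_lemmatizer()
#' lem$transform(c("studying", "studied", "studies", "strains", "."))
#' @export
builtin_lemmatizer <- function() {
  irregular <- c(
    is = "be", are = "be", was = "be", were = "be", been = "be", am = "be",
    has = "have", had = "have", having = "have",
    does = "do", did = "do", done = "do",
    goes = "go", went = "go", gone = "go",
    children = "child", mice = "mouse", men = "man", women = "woman",
    bacteria = "bacterium", media = "medium", data = "data",
    genera = "genus", fungi = "fungus", criteria = "criterion",
    found = "find", shown = "show", showed = "show", given = "give",
    taken = "take", made = "make", used = "use", using = "use",
    better = "good", worse = "bad"
  )
  # plural-looking words that must keep their final s
  keep_s <- c(
    "species", "perhaps", "thus", "always", "whereas", "news", "series",
    "sometimes", "towards", "besides", "across", "lens", "mumps")

  transform <- function(tokens) {
    if (length(tokens) == 0) return(character(0))
    word <- is_word_token(tokens)
    out <- tokens
    out[word] <- vapply(tolower(tokens[word]), lemmatize_word,
                        character(1), irregular = irregular,
                        keep_s = keep_s, USE.NAMES = FALSE)
    out
  }
  lemmatizer_plugin("builtin", transform)
}

lemmatize_word <- function(w, irregular, keep_s) {
  if (!is.na(irregular[w])) return(unname(irregular[w]))
  n <- nchar(w)
  if (w %in% keep_s) return(w)
  # -ies -> -y  (studies -> study), -ied -> -y (studied -> study)
  if (n > 4 && endsWith(w, "ies")) return(paste0(substr(w, 1, n - 3), "y"))
  if (n > 4 && endsWith(w, "ied")) return(paste0(substr(w, 1, n - 3), "y"))
  # -ing with undoubling (running -> run); require a stem of >= 3 chars
  if (n > 5 && endsWith(w, "ing")) {
    stem <- substr(w, 1, n - 3)
    return(undouble(stem))
  }
  # -ed (treated -> treat); require a stem of >= 3 chars
  if (n > 4 && endsWith(w, "ed") && !endsWith(w, "eed")) {
    stem <- substr(w, 1, n - 2)
    return(undouble(stem))
  }
  # plural -es after sibilants (boxes -> box), else plain -s
  if (n > 4 && grepl("(ches|shes|sses|xes|zes)$", w)) {
    return(substr(w, 1, n - 2))
  }
  if (n > 3 && endsWith(w, "s") && !grepl("(ss|us|is)$", w)) {
    return(substr(w, 1, n - 1))
  }
  w
}

# Drop a doubled final consonant left by -ing/-ed stripping (runn -> run),
# keeping legitimate doubles like -ll and -ss (fall, press).
undouble <- function(stem) {
  n <- nchar(stem)
  if (n >= 3) {
    last <- substr(stem, n, n)
    prev <- substr(stem, n - 1, n - 1)
    if (last == prev && grepl("[bdfgmnprt]", last)) {
      return(substr(stem, 1, n - 1))
    }
  }
  stem
}

#' Define a lemmatizer plugin
#'
#' A plugin is a named, deterministic token-to-lemma transform; it must be
#' the identity on punctuation, number and symbol tokens. If the transform
#' fails on a batch, [lemmatize()] falls back to the lowercased surface
#' forms with a warning.
#'
#' @param name Plugin name.
#' @param transform Function mapping a character vector of tokens to a
#'   character vector of lemmas of the same length.
#' @return An object of class `lemmatizer_plugin`.
#' @export
lemmatizer_plugin <- function(name, transform) {
  stopifnot(is.character(name), is.function(transform))
  structure(list(name = name, transform = transform),
            class = "lemmatizer_plugin")
}

#' Resolve a lemmatizer by name
#'
#' @param lemmatizer A `lemmatizer_plugin` or the name `"builtin"`.
#' @return A `lemmatizer_plugin`.
#' @export
resolve_lemmatizer <- function(lemmatizer = "builtin") {
  if (inherits(lemmatizer, "lemmatizer_plugin")) return(lemmatizer)
  if (identical(lemmatizer, "builtin")) return(builtin_lemmatizer())
  stop_litthemes(sprintf("unknown lemmatizer '%s'", lemmatizer),
                 "litthemes_parameter_error")
}

#' Lemmatize a token sequence
#'
#' Applies a lemmatizer plugin to a token vector, preserving length and
#' order. Word tokens come back lowercased lemmas; non-word tokens are
#' unchanged. A plugin failure falls back to lowercased surface forms.
#'
#' @param tokens Character vector of tokens from [tokenize()].
#' @param lemmatizer Plugin or name, see [resolve_lemmatizer()].
#' @return Character vector of lemmas, same length as `tokens`.
#' @export
lemmatize <- function(tokens, lemmatizer = "builtin") {
  plugin <- resolve_lemmatizer(lemmatizer)
  out <- tryCatch(plugin$transform(tokens), error = function(e) {
    warn(sprintf("lemmatizer '%s' failed (%s); falling back to lowercase",
                 plugin$name, conditionMessage(e)))
    ifelse(is_word_token(tokens), tolower(tokens), tokens)
  })
  if (length(out) != length(tokens)) {
    stop_litthemes(sprintf(
      "lemmatizer '%s' changed the token count (%d -> %d)",
      plugin$name, length(tokens), length(out)),
      "litthemes_consistency_error")
  }
  out
}

#' Tokenize and lemmatize a whole corpus
#'
#' Assembles the title+abstract document for every record, tokenizes it and
#' lemmatizes the tokens, returning one row per record with the lemma
#' sequence as a list-column. Stop words are not removed: the full token
#' inventory (lemmas, punctuation, numbers, symbols) feeds the vectorizer.
#'
#' @param corpus Corpus tibble from [read_corpus()] or [generate_corpus()].
#' @param lemmatizer Plugin or name, see [resolve_lemmatizer()].
#' @return A tibble with columns `id` and `tokens` (list of character
#'   vectors), in corpus order.
#' @export
tokenize_corpus <- function(corpus, lemmatizer = "builtin") {
  validate_corpus(corpus)
  plugin <- resolve_lemmatizer(lemmatizer)
  tokens <- purrr::map2(corpus$title, corpus$abstract, function(ti, ab) {
    lemmatize(tokenize(assemble_document(ti, ab)), plugin)
  })
  tibble(id = corpus$id, tokens = tokens)
}
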