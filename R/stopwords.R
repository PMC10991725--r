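#' English stop-word list
#'
#' A fixed, versioned list of common English function words used when
#' normalising manual cluster labels for the label-overlap evaluation.
#' Stop words are never removed before vectorization; they matter only in
#' [evaluate_label_overlap()].
#'
#' @return Character vector of lowercase stop words.
#' @export
english_stopwords <- function() {
  c("a", "about", "above", "after", "again", "against", "all", "also", "am",
    "an", "and", "any", "are", "as", "at", "be", "because", "been", "before",
    "being", "below", "between", "both", "but", "by", "can", "cannot",
    "could", "did", "do", "does", "doing", "down", "during", "each",
    "especially", "etc", "few", "for", "from", "further", "had", "has",
    "have", "having", "he", "her", "here", "hers", "him", "his", "how", "i",
    "if", "in", "into", "is", "it", "its", "itself", "just", "mainly",
    "may", "me", "might", "more", "most", "must", "my", "no", "nor", "not",
    "now", "of", "off", "on", "once", "only", "or", "other", "our", "ours",
    "out", "over", "own", "same", "she", "should", "so", "some", "such",
    "than", "that", "the", "their", "theirs", "them", "then", "there",
    "these", "they", "this", "those", "through", "to", "too", "under",
    "until", "up", "upon", "very", "was", "we", "were", "what", "when",
    "where", "which", "while", "who", "whom", "why", "will", "with",
    "within", "without", "would", "you", "your", "yours")
}
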