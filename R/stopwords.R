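# Standard English stop list (the usual 179-word NLTK-style list). Because
# preprocessing replaces punctuation with spaces before tokenization,
# contraction fragments ("don t" -> "don", "t") are covered by the
# single-letter and clitic entries below.
.default_stopwords <- c(
  "i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you",
  "your", "yours", "yourself", "yourselves", "he", "him", "his", "himself",
  "she", "her", "hers", "herself", "it", "its", "itself", "they", "them",
  "their", "theirs", "themselves", "what", "which", "who", "whom", "this",
  "that", "these", "those", "am", "is", "are", "was", "were", "be", "been",
  "being", "have", "has", "had", "having", "do", "does", "did", "doing",
  "a", "an", "the", "and", "but", "if", "or", "because", "as", "until",
  "while", "of", "at", "by", "for", "with", "about", "against", "between",
  "into", "through", "during", "before", "after", "above", "below", "to",
  "from", "up", "down", "in", "out", "on", "off", "over", "under", "again",
  "further", "then", "once", "here", "there", "when", "where", "why", "how",
  "all", "any", "both", "each", "few", "more", "most", "other", "some",
  "such", "no", "nor", "not", "only", "own", "same", "so", "than", "too",
  "very", "s", "t", "can", "will", "just", "don", "should", "now", "d",
  "ll", "m", "o", "re", "ve", "y", "ain", "aren", "couldn", "didn",
  "doesn", "hadn", "hasn", "haven", "isn", "ma", "mightn", "mustn",
  "needn", "shan", "shouldn", "wasn", "weren", "won", "wouldn"
)

#' Default English stop list
#'
#' Returns the stop list used by [preprocess()] and [compile_lexicon()]:
#' a standard English list optionally augmented with user-supplied words
#' (mirroring corpus-specific additions made during topic-model tuning).
#' One list serves both entity matching and topic modeling.
#'
#' @param extra character vector of additional stop words (lowercased).
#' @return character vector of lowercase stop words.
#' @export
ndkg_stopwords <- function(extra = character()) {
  unique(c(.default_stopwords, tolower(extra)))
}

#' Read a stop-list file
#'
#' One word per line, UTF-8. Blank lines and lines starting with `#` are
#' ignored. The result is merged with the default English list unless
#' `merge_default = FALSE`.
#'
#' @param path path to the stop-list file.
#' @param merge_default also include the built-in English list?
#' @return character vector of stop words.
#' @export
read_stoplist <- function(path, merge_default = TRUE) {
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  words <- tolower(lines[nzchar(lines) & !startsWith(lines, "#")])
  if (merge_default) ndkg_stopwords(words) else unique(words)
}
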