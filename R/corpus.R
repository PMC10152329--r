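#' Load a corpus of cleaned resource documents
#'
#' Reads a corpus in one of two layouts: a JSONL file (one JSON object per
#' line with keys `url` and `text`, optional `source`, `parent_url`,
#' `resource_type` and `doc_id`) or a directory of UTF-8 `.txt` files (one
#' document per file, `doc_id` = file name without extension). Documents
#' are expected to be cleaned plain text; scraping and boilerplate removal
#' happen upstream of this package.
#'
#' Malformed records are skipped with a warning; records with empty text
#' are skipped and counted in a message. Duplicate document ids are an
#' error. When `doc_id` is missing it defaults to a hash of the URL.
#'
#' @param path path to the JSONL file or the document directory.
#' @param format `"jsonl"` or `"directory"`.
#' @return a data frame of class `ndkg_corpus` with columns `doc_id`,
#'   `url`, `source` (`caregiver`, `inform_alberta` or `other`),
#'   `parent_id`, `resource_type` (`webpage`, `video` or `pdf`) and `text`.
#' @export
load_corpus <- function(path, format = c("jsonl", "directory")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_ndkg("corpus path does not exist: ", path)
  recs <- if (format == "jsonl") .load_jsonl(path) else .load_dir(path)
  empty <- vapply(recs, function(r) !nzchar(trimws(r$text %||% "")), logical(1))
  if (any(empty)) {
    message(sum(empty), " record(s) with empty text skipped")
    recs <- recs[!empty]
  }
  if (!length(recs)) stop_ndkg("no valid documents in corpus")
  df <- data.frame(
    doc_id = vapply(recs, function(r) as.character(r$doc_id %||% string_hash(r$url)), character(1)),
    url = vapply(recs, function(r) as.character(r$url), character(1)),
    source = vapply(recs, function(r) as.character(r$source %||% "other"), character(1)),
    parent_id = vapply(recs, function(r) as.character(r$parent_id %||% NA_character_), character(1)),
    resource_type = vapply(recs, function(r) as.character(r$resource_type %||% "webpage"), character(1)),
    text = vapply(recs, function(r) as.character(r$text), character(1)),
    stringsAsFactors = FALSE
  )
  dup <- unique(df$doc_id[duplicated(df$doc_id)])
  if (length(dup)) {
    stop_ndkg("duplicate doc_id in corpus: ", paste(dup, collapse = ", "))
  }
  bad_src <- !df$source %in% c("caregiver", "inform_alberta", "other")
  if (any(bad_src)) df$source[bad_src] <- "other"
  bad_rt <- !df$resource_type %in% c("webpage", "video", "pdf")
  if (any(bad_rt)) df$resource_type[bad_rt] <- "webpage"
  class(df) <- c("ndkg_corpus", "data.frame")
  df
}

.load_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  ok <- logical(length(lines))
  for (i in seq_along(lines)) {
    r <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(r) || is.null(r$url) || is.null(r$text)) {
      warning("skipping malformed corpus record at line ", i, call. = FALSE)
      next
    }
    if (!is.null(r$parent_url) && is.null(r$parent_id)) {
      r$parent_id <- string_hash(r$parent_url)
    }
    recs[[i]] <- r
    ok[i] <- TRUE
  }
  recs[ok]
}

.load_dir <- function(path) {
  files <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
  if (!length(files)) stop_ndkg("no .txt files under ", path)
  lapply(files, function(f) {
    list(doc_id = tools::file_path_sans_ext(basename(f)),
         url = basename(f),
         text = paste(readLines(f, encoding = "UTF-8", warn = FALSE),
                      collapse = "\n"))
  })
}

#' Preprocess text into a token stream
#'
#' Applies the five normalization steps used throughout the pipeline:
#' punctuation removal (every punctuation or symbol character, including
#' hyphens, is replaced by a space, splitting hyphenated words), lowercasing,
#' whitespace tokenization, lemmatization ([lemmatize()]), and stop-word
#' removal. Stop words are filtered on the lemmatized form. The identical
#' normalization must be applied to documents, lexicon surface forms and
#' queries so that phrases meet in lemma space.
#'
#' @param text a single character string (or a Document row's text).
#' @param stops character vector of stop words, see [ndkg_stopwords()].
#' @param doc_id optional document id carried into the result.
#' @param lemma_extra optional extra lemma pairs, see [lemmatize()].
#' @return an object of class `ndkg_tokens`: list with `doc_id`, `tokens`
#'   (lemmas, in order) and `offsets` (data frame of `start`/`end`
#'   character spans of each kept token in the input text).
#' @examples
#' preprocess("The Children were running.", ndkg_stopwords())$tokens
#' @export
preprocess <- function(text, stops = ndkg_stopwords(), doc_id = NA_character_,
                       lemma_extra = NULL) {
  stopifnot(is.character(text), length(text) == 1)
  clean <- gsub("[\\p{P}\\p{S}]", " ", text, perl = TRUE)
  low <- tolower(clean)
  m <- gregexpr("\\S+", low, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(.token_stream(doc_id, character(), integer(), integer()))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  raw <- substring(low, starts, starts + lens - 1L)
  lemmas <- lemmatize(raw, extra = lemma_extra)
  keep <- nzchar(lemmas) & !(lemmas %in% stops)
  .token_stream(doc_id, lemmas[keep], starts[keep], (starts + lens - 1L)[keep])
}

.token_stream <- function(doc_id, tokens, start, end) {
  structure(
    list(doc_id = doc_id, tokens = tokens,
         offsets = data.frame(start = start, end = end)),
    class = "ndkg_tokens"
  )
}

#' @export
print.ndkg_tokens <- function(x, ...) {
  cat("<ndkg_tokens> doc:", x$doc_id, "-", length(x$tokens), "tokens\n")
  invisible(x)
}

#' Preprocess every document of a corpus
#'
#' @param corpus an `ndkg_corpus` data frame from [load_corpus()].
#' @inheritParams preprocess
#' @return named list of `ndkg_tokens`, one per document.
#' @export
preprocess_corpus <- function(corpus, stops = ndkg_stopwords(),
                              lemma_extra = NULL) {
  out <- lapply(seq_len(nrow(corpus)), function(i) {
    preprocess(corpus$text[i], stops, doc_id = corpus$doc_id[i],
               lemma_extra = lemma_extra)
  })
  names(out) <- corpus$doc_id
  out
}
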