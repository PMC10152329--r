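# Dictionary-based named entity recognition: controlled-vocabulary surface
# forms are compiled (with the corpus lemmatizer) into an exact phrase
# matcher over lemma sequences, applied left-to-right with a longest-match,
# non-overlapping rule -- the behavior of common rule-based matchers.

.vocab_levels <- c("HPO", "UMLS", "ERIC", "AIRS", "AGE", "LOCATION", "BEHAVIOR")

#' Read a controlled-vocabulary lexicon table
#'
#' CSV with columns `surface`, `canonical`, `vocab` (one of HPO, UMLS,
#' ERIC, AIRS, AGE, LOCATION, BEHAVIOR) and optional `concept_id` and
#' `behavior_category`. `behavior_category` must be present exactly for
#' BEHAVIOR rows and must be one of [behavior_categories()].
#'
#' @param path CSV path (one file per vocabulary, or one combined file).
#' @return data frame of lexicon entries.
#' @export
read_lexicon <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_lexicon(df)
}

#' Validate lexicon entries
#'
#' @param entries data frame with at least `surface`, `canonical`, `vocab`.
#' @return the entries, normalized (missing optional columns filled with NA).
#' @export
validate_lexicon <- function(entries) {
  need <- c("surface", "canonical", "vocab")
  miss <- setdiff(need, names(entries))
  if (length(miss)) stop_ndkg("lexicon missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(entries$concept_id)) entries$concept_id <- NA_character_
  if (is.null(entries$behavior_category)) entries$behavior_category <- NA_character_
  entries$concept_id[!nzchar(entries$concept_id %||% "") | is.na(entries$concept_id)] <- NA_character_
  entries$behavior_category[!is.na(entries$behavior_category) & !nzchar(entries$behavior_category)] <- NA_character_
  bad <- !entries$vocab %in% .vocab_levels
  if (any(bad)) stop_ndkg("unknown vocab label(s): ", paste(unique(entries$vocab[bad]), collapse = ", "))
  if (!all(nzchar(entries$surface))) stop_ndkg("empty surface form in lexicon")
  beh <- entries$vocab == "BEHAVIOR"
  if (any(beh & is.na(entries$behavior_category))) {
    stop_ndkg("BEHAVIOR entries require behavior_category")
  }
  if (any(!beh & !is.na(entries$behavior_category))) {
    stop_ndkg("behavior_category only allowed for BEHAVIOR entries")
  }
  bad_cat <- beh & !entries$behavior_category %in% behavior_categories()
  if (any(bad_cat)) {
    stop_ndkg("unknown behavior_category: ",
              paste(unique(entries$behavior_category[bad_cat]), collapse = ", "))
  }
  entries[c("surface", "canonical", "vocab", "concept_id", "behavior_category")]
}

#' Compile a lexicon into a phrase matcher
#'
#' Every surface form is preprocessed exactly like document text
#' (punctuation removal, lowercasing, lemmatization, stop-word removal) so
#' that lexicon phrases and document tokens meet in lemma space. Entries
#' whose surface reduces to an empty token sequence are dropped with a
#' warning. Colliding patterns (identical lemma sequence from different
#' entries) are retained as a set: a match emits all colliding entries.
#'
#' @param entries lexicon data frame (see [read_lexicon()]).
#' @param stops stop list used for the corpus.
#' @param lemma_extra optional extra lemma pairs.
#' @return object of class `ndkg_lexicon`: `patterns` (named list mapping
#'   space-joined lemma sequences to entry data frames) and
#'   `max_pattern_length`.
#' @export
compile_lexicon <- function(entries, stops = ndkg_stopwords(), lemma_extra = NULL) {
  entries <- validate_lexicon(entries)
  if (!nrow(entries)) stop_ndkg("empty lexicon")
  toks <- lapply(entries$surface, function(s) preprocess(s, stops, lemma_extra = lemma_extra)$tokens)
  len <- lengths(toks)
  if (any(len == 0)) {
    warning("dropping ", sum(len == 0), " lexicon entr(ies) whose surface reduces to an empty token sequence: ",
            paste(utils::head(entries$surface[len == 0], 5), collapse = ", "),
            call. = FALSE)
    entries <- entries[len > 0, , drop = FALSE]
    toks <- toks[len > 0]
    len <- len[len > 0]
  }
  if (!nrow(entries)) stop_ndkg("no lexicon entries survive preprocessing")
  keys <- vapply(toks, paste, character(1), collapse = " ")
  patterns <- split(entries, keys)
  structure(
    list(patterns = patterns, max_pattern_length = max(len)),
    class = "ndkg_lexicon"
  )
}

#' @export
print.ndkg_lexicon <- function(x, ...) {
  cat("<ndkg_lexicon>", length(x$patterns), "patterns, max length",
      x$max_pattern_length, "\n")
  invisible(x)
}

#' Match lexicon entities in a token stream
#'
#' Scans left to right; at each position the longest matching pattern wins
#' and its span is consumed, so mentions never overlap. All entries of a
#' colliding pattern are emitted at the same span. The token stream must
#' have been preprocessed with the same stop list and lemmatizer as the
#' lexicon.
#'
#' @param ts an `ndkg_tokens` object.
#' @param lex a compiled lexicon.
#' @return data frame of mentions: `doc_id`, `canonical`, `vocab`,
#'   `concept_id`, `behavior_category`, `start`, `end` (half-open token
#'   span, 1-based).
#' @export
match_entities <- function(ts, lex) {
  tokens <- ts$tokens
  n <- length(tokens)
  out <- list()
  i <- 1L
  maxlen <- lex$max_pattern_length
  while (i <= n) {
    matched <- FALSE
    for (L in seq(min(maxlen, n - i + 1L), 1L)) {
      key <- paste(tokens[i:(i + L - 1L)], collapse = " ")
      hit <- lex$patterns[[key]]
      if (!is.null(hit)) {
        hit$start <- i
        hit$end <- i + L
        out[[length(out) + 1L]] <- hit
        i <- i + L
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(surface = character(), canonical = character(),
               vocab = character(), concept_id = character(),
               behavior_category = character(),
               start = integer(), end = integer())
  res$doc_id <- if (nrow(res)) ts$doc_id else character(0)
  rownames(res) <- NULL
  res[c("doc_id", "canonical", "vocab", "concept_id", "behavior_category",
        "start", "end")]
}

#' Match entities across a whole corpus
#'
#' @param streams named list of token streams from [preprocess_corpus()].
#' @param lex compiled lexicon.
#' @return one mentions data frame (rows from all documents).
#' @export
match_corpus <- function(streams, lex) {
  do.call(rbind, c(lapply(streams, match_entities, lex = lex),
                   make.row.names = FALSE))
}

#' Collapse challenging-behavior mentions onto their category
#'
#' The ten challenging-behavior graph nodes are the categories, not the
#' individual phrases; this maps each BEHAVIOR mention's canonical term to
#' its `behavior_category` before counting. Mentions of other vocabularies
#' pass through unchanged.
#'
#' @param mentions mentions data frame from [match_entities()].
#' @return mentions with BEHAVIOR canonicals replaced by the category.
#' @export
collapse_behavior <- function(mentions) {
  beh <- mentions$vocab == "BEHAVIOR"
  mentions$canonical[beh] <- mentions$behavior_category[beh]
  mentions
}

#' Count per-document entity frequencies
#'
#' @param mentions mentions data frame (all documents).
#' @param doc_ids optional full vector of corpus document ids, so that
#'   documents without mentions appear with a distinct-entity count of 0
#'   (they enter the pivot average).
#' @return list of class `ndkg_freq`: `tf` (data frame `doc_id`,
#'   `canonical`, `vocab`, `tf`) and `distinct_entities` (named integer
#'   vector over `doc_ids`).
#' @export
count_frequencies <- function(mentions, doc_ids = NULL) {
  if (is.null(doc_ids)) doc_ids <- unique(mentions$doc_id)
  if (nrow(mentions)) {
    key <- paste(mentions$doc_id, mentions$vocab, mentions$canonical, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    tf <- data.frame(
      doc_id = vapply(parts, `[`, character(1), 1),
      vocab = vapply(parts, `[`, character(1), 2),
      canonical = vapply(parts, `[`, character(1), 3),
      tf = as.integer(tab),
      stringsAsFactors = FALSE
    )
    tf <- tf[order(tf$doc_id, tf$vocab, tf$canonical), c("doc_id", "canonical", "vocab", "tf")]
    rownames(tf) <- NULL
  } else {
    tf <- data.frame(doc_id = character(), canonical = character(),
                     vocab = character(), tf = integer())
  }
  distinct <- integer(length(doc_ids))
  names(distinct) <- doc_ids
  if (nrow(tf)) {
    d <- table(tf$doc_id)
    distinct[names(d)] <- as.integer(d)
  }
  structure(list(tf = tf, distinct_entities = distinct), class = "ndkg_freq")
}

#' Document-level entity co-occurrences
#'
#' Counts, for every unordered pair of entity keys (`vocab:canonical`), the
#' number of documents in which both have at least one mention. Mention
#' multiplicity within a document does not matter; zero-count pairs are
#' omitted.
#'
#' @param mentions mentions data frame (all documents).
#' @param scope counting scope; only `"document"` is defined.
#' @return data frame `a`, `b`, `count` with `a < b` lexicographically.
#' @export
cooccurrences <- function(mentions, scope = "document") {
  stopifnot(identical(scope, "document"))
  if (!nrow(mentions)) {
    return(data.frame(a = character(), b = character(), count = integer()))
  }
  keys_by_doc <- lapply(split(entity_key(mentions$vocab, mentions$canonical),
                              mentions$doc_id), unique)
  pairs <- list()
  for (ks in keys_by_doc) {
    if (length(ks) < 2) next
    ks <- sort(ks)
    cmb <- utils::combn(ks, 2)
    pairs[[length(pairs) + 1L]] <- paste(cmb[1, ], cmb[2, ], sep = "\r")
  }
  if (!length(pairs)) {
    return(data.frame(a = character(), b = character(), count = integer()))
  }
  tab <- table(unlist(pairs))
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    a = vapply(parts, `[`, character(1), 1),
    b = vapply(parts, `[`, character(1), 2),
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  out[order(out$a, out$b), ]
}
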