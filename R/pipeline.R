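#' Annotate a corpus and build its knowledge graph
#'
#' End-to-end convenience wrapper: preprocess the corpus, match lexicon
#' entities (collapsing challenging-behavior phrases to their categories),
#' compute pivoted-normalization relevance weights and document
#' co-occurrences, fit the hierarchical topic model, detect locations,
#' optionally train/apply the multilabel category classifier, and
#' assemble the knowledge graph.
#'
#' @param corpus an `ndkg_corpus`.
#' @param lexicon lexicon data frame (see [read_lexicon()]).
#' @param gazetteer an `ndkg_gazetteer`, or NULL to skip locations.
#' @param labels an `ndkg_labeled` training set for the category
#'   classifier, or NULL to skip classification.
#' @param stops stop list (one list for NER and topic modeling).
#' @param K0 root topic count of the hierarchical topic model; NULL skips
#'   topic modeling.
#' @param threshold HTM document threshold per topic.
#' @param lda_cfg an [lda_config()].
#' @param clf_cfg a [classifier_config()].
#' @param slope,log_base relevance parameters (pivot is computed from the
#'   collection).
#' @param floor sparsification floor for topic-family edge weights.
#' @param split_seed seed of the stratified classifier split.
#' @return list of class `ndkg_annotation`: `graph`, plus the intermediate
#'   artifacts (`streams`, `mentions`, `freq`, `params`, `relevance`,
#'   `cooccur`, `hierarchy`, `leaves`, `locations`, `classifier`,
#'   `categories`, `lexicon` (compiled)).
#' @export
annotate_corpus <- function(corpus, lexicon, gazetteer = NULL, labels = NULL,
                            stops = ndkg_stopwords(), K0 = 5, threshold = 300,
                            lda_cfg = lda_config(), clf_cfg = classifier_config(),
                            slope = 0.2, log_base = "natural", floor = 1e-3,
                            split_seed = 1) {
  streams <- preprocess_corpus(corpus, stops)
  lex <- compile_lexicon(lexicon, stops)
  mentions <- collapse_behavior(match_corpus(streams, lex))
  freq <- count_frequencies(mentions, doc_ids = corpus$doc_id)
  params <- relevance_params(slope = slope, pivot = compute_pivot(freq),
                             log_base = log_base)
  rel <- relevance_scores(freq, params)
  cooc <- cooccurrences(mentions)

  hierarchy <- NULL; leaves <- NULL
  if (!is.null(K0)) {
    hierarchy <- hierarchical_topic_model(streams, K0, threshold, lda_cfg)
    leaves <- leaf_topics(hierarchy)
  }

  locations <- NULL
  if (!is.null(gazetteer)) {
    locations <- list()
    for (i in seq_len(nrow(corpus))) {
      lm <- detect_locations(corpus$text[i], gazetteer, stops,
                             doc_id = corpus$doc_id[i])
      if (nrow(lm)) locations[[corpus$doc_id[i]]] <- location_weights(lm)
    }
  }

  classifier <- NULL; categories <- NULL
  if (!is.null(labels)) {
    sp <- split_dataset(labels, seed = split_seed)
    classifier <- train_multilabel(sp$train, sp$val, clf_cfg, stops)
    classifier$threshold <- as.numeric(select_threshold(classifier, sp$val))
    P <- predict_proba(classifier, corpus$text)
    hits <- which(P > classifier$threshold, arr.ind = TRUE)
    if (nrow(hits)) {
      categories <- data.frame(
        doc_id = corpus$doc_id[hits[, 1]],
        category = colnames(P)[hits[, 2]],
        prob = P[hits], stringsAsFactors = FALSE)
    }
  }

  graph <- build_graph(
    corpus, rel, cooc, leaves, hierarchy, categories, locations,
    params = list(pivot = params$pivot, slope = params$slope,
                  log_base = params$log_base, floor = floor,
                  K0 = K0, threshold = threshold,
                  lda_seed = lda_cfg$seed),
    lexicon = lexicon
  )
  structure(
    list(graph = graph, streams = streams, mentions = mentions, freq = freq,
         params = params, relevance = rel, cooccur = cooc,
         hierarchy = hierarchy, leaves = leaves, locations = locations,
         classifier = classifier, categories = categories, lexicon = lex),
    class = "ndkg_annotation"
  )
}

#' @export
print.ndkg_annotation <- function(x, ...) {
  cat("<ndkg_annotation>\n")
  print(x$graph)
  invisible(x)
}
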