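# Free-text retrieval over the knowledge graph. A query is parsed into
# criteria -- lexicon entities, topic-vocabulary unigrams, and the intent
# classifier's challenging-behavior category -- and every resource adjacent
# to at least one criterion node is scored by ordered weighted averaging
# (OWA) of its criterion edge weights. OWA weights come from a regular
# increasing monotone (RIM) linguistic quantifier Q: w_i = Q(i/n) -
# Q((i-1)/n) applied to the values sorted in descending order, so MOST
# rewards resources that satisfy many criteria reasonably well rather
# than one criterion extremely well.

#' RIM linguistic quantifier
#'
#' Regular increasing monotone quantifier Q on [0, 1] with Q(0) = 0,
#' Q(1) = 1. `most` and `some` are piecewise linear between `a` and `b`
#' (classical parameters (0.3, 0.8) and (0, 0.5)); `all` is the indicator
#' of 1 (minimum); `at_least_n` puts all weight on the n-th largest value;
#' `identity` gives the arithmetic mean.
#'
#' @param kind one of `"most"`, `"some"`, `"all"`, `"at_least_n"`,
#'   `"identity"`.
#' @param a,b breakpoints in [0, 1] for `most`/`some`.
#' @param n the n of `at_least_n`.
#' @return object of class `ndkg_quantifier`.
#' @export
rim_quantifier <- function(kind = c("most", "some", "all", "at_least_n", "identity"),
                           a = NULL, b = NULL, n = NULL) {
  kind <- match.arg(kind)
  if (kind == "most") { a <- a %||% 0.3; b <- b %||% 0.8 }
  if (kind == "some") { a <- a %||% 0; b <- b %||% 0.5 }
  if (kind == "at_least_n" && is.null(n)) stop_ndkg("at_least_n needs n")
  if (!is.null(a) && !is.null(b)) stopifnot(a >= 0, b <= 1, a < b)
  structure(list(kind = kind, a = a, b = b, n = n), class = "ndkg_quantifier")
}

# Q as a function, given the number of criteria (needed by at_least_n).
.quantifier_fn <- function(q, n_total) {
  switch(q$kind,
         identity = function(x) x,
         all = function(x) as.numeric(x >= 1),
         at_least_n = {
           k <- min(q$n, n_total)
           function(x) as.numeric(x >= k / n_total - 1e-12)
         },
         function(x) {   # most / some: piecewise linear
           pmin(1, pmax(0, (x - q$a) / (q$b - q$a)))
         })
}

#' OWA weights from a RIM quantifier
#'
#' `w_i = Q(i/n) - Q((i-1)/n)`; the weights are non-negative and sum to 1.
#'
#' @param q an [rim_quantifier()].
#' @param n number of criteria (length of the value vector).
#' @return numeric weight vector of length `n`.
#' @export
owa_weights <- function(q, n) {
  stopifnot(n >= 1)
  Q <- .quantifier_fn(q, n)
  i <- seq_len(n)
  Q(i / n) - Q((i - 1) / n)
}

#' OWA aggregation
#'
#' Yager's ordered weighted average: the values are sorted in descending
#' order and dotted with the weight vector.
#'
#' @param w OWA weights (length n, summing to 1).
#' @param values numeric vector of length n.
#' @return scalar aggregate, bounded by min and max of `values`.
#' @export
owa_aggregate <- function(w, values) {
  if (length(w) != length(values)) {
    stop_ndkg("length mismatch: ", length(w), " weights vs ",
              length(values), " values")
  }
  sum(w * sort(values, decreasing = TRUE))
}

#' Parse a free-text query into graph criteria
#'
#' Runs the corpus preprocessing and lexicon matcher on the query, keeps
#' query tokens present in the topic vocabulary as unigram criteria, and
#' appends the intent classifier's challenging-behavior category.
#'
#' @param text query text.
#' @param lex compiled lexicon ([compile_lexicon()]).
#' @param topic_vocab character vector of unigram-node words (the topic
#'   vocabulary), or NULL to skip unigram criteria.
#' @param intent an `ndkg_intent` model, or NULL to skip intent.
#' @param stops stop list (must match the build).
#' @return list of class `ndkg_query`: `entities` (mentions data frame
#'   with BEHAVIOR collapsed to categories), `unigrams`,
#'   `behavior_category` (or NA).
#' @export
parse_query <- function(text, lex, topic_vocab = NULL, intent = NULL,
                        stops = ndkg_stopwords()) {
  ts <- preprocess(text, stops, doc_id = "query")
  entities <- if (length(ts$tokens)) {
    collapse_behavior(match_entities(ts, lex))
  } else {
    match_entities(.token_stream("query", character(), integer(), integer()), lex)
  }
  unigrams <- if (is.null(topic_vocab)) character() else
    unique(ts$tokens[ts$tokens %in% topic_vocab])
  behavior <- if (!is.null(intent) && nzchar(trimws(text))) {
    classify_intent(intent, text)
  } else NA_character_
  structure(list(entities = entities, unigrams = unigrams,
                 behavior_category = behavior),
            class = "ndkg_query")
}

#' @export
print.ndkg_query <- function(x, ...) {
  cat("<ndkg_query>", nrow(x$entities), "entities;",
      length(x$unigrams), "unigrams; intent:",
      x$behavior_category, "\n")
  invisible(x)
}

# Criterion node ids of a parsed query, with items that have no node in
# the graph dropped (with a notice).
.criterion_nodes <- function(kg, terms) {
  ids <- character()
  if (nrow(terms$entities)) {
    e <- unique(terms$entities[c("vocab", "canonical")])
    ids <- c(ids, node_id_entity(e$vocab, e$canonical))
  }
  if (!is.na(terms$behavior_category)) {
    ids <- c(ids, node_id_entity("BEHAVIOR", terms$behavior_category))
  }
  ids <- c(ids, node_id_unigram(terms$unigrams))
  ids <- unique(ids)
  present <- ids %in% kg$nodes$node_id
  if (any(!present)) {
    message("dropping ", sum(!present), " query criterion(s) without a graph node")
  }
  ids[present]
}

#' Retrieve candidate resources and their criterion weight vectors
#'
#' A candidate is any resource adjacent, by a CONTAINS or containsNgram
#' edge, to at least one criterion node. Each candidate's vector has one
#' slot per criterion, holding the edge weight or 0 when the edge is
#' absent (a partially matching resource keeps a comparable vector and is
#' softly penalized by quantifiers like MOST).
#'
#' @param kg an `ndkg_graph`.
#' @param terms an `ndkg_query` from [parse_query()].
#' @return matrix (resources x criteria) of weights, rownames = resource
#'   node ids, colnames = criterion node ids; zero rows if nothing matches.
#' @export
retrieve_candidates <- function(kg, terms) {
  crit <- .criterion_nodes(kg, terms)
  if (!length(crit)) {
    return(matrix(numeric(), 0, 0))
  }
  ed <- kg$edges
  rel_ok <- ed$rel %in% c("CONTAINS", "containsNgram")
  hit <- ed[rel_ok & ed$dst %in% crit, , drop = FALSE]
  cands <- sort(unique(hit$src))
  M <- matrix(0, length(cands), length(crit),
              dimnames = list(cands, crit))
  if (nrow(hit)) {
    # several edges between the same pair cannot occur by construction,
    # but keep the max defensively
    for (i in seq_len(nrow(hit))) {
      M[hit$src[i], hit$dst[i]] <- max(M[hit$src[i], hit$dst[i]], hit$weight[i])
    }
  }
  M
}

#' Rank resources for a free-text query
#'
#' Composes [parse_query()], [retrieve_candidates()] and per-candidate
#' [owa_aggregate()] (n = number of criteria), sorts by descending score
#' with ties broken by ascending document id, and truncates to `top_n`.
#'
#' @param kg an `ndkg_graph`.
#' @param text query text.
#' @param lex compiled lexicon used at build time.
#' @param topic_vocab unigram vocabulary of the graph (defaults to the
#'   graph's Unigram node labels).
#' @param intent intent model or NULL.
#' @param quantifier an [rim_quantifier()]; MOST by default.
#' @param top_n rows to return (default 10).
#' @param rescale min-max rescale each criterion family (entity, unigram,
#'   behavior) to [0, 1] before aggregation; off by default, leaving the
#'   weight families on their native scales.
#' @param stops stop list.
#' @return data frame of class `ndkg_ranking`: `doc_id`, `url`, `score`,
#'   `categories` (pipe-joined category memberships); per-criterion
#'   weights in `attr(, "criteria")`.
#' @export
rank_resources <- function(kg, text, lex, topic_vocab = NULL, intent = NULL,
                           quantifier = rim_quantifier("most"), top_n = 10,
                           rescale = FALSE, stops = ndkg_stopwords()) {
  if (is.null(topic_vocab)) {
    topic_vocab <- kg$nodes$label[kg$nodes$node_type == "Unigram"]
  }
  terms <- parse_query(text, lex, topic_vocab, intent, stops)
  M <- retrieve_candidates(kg, terms)
  if (!nrow(M)) {
    message("no results for query")
    out <- data.frame(doc_id = character(), url = character(),
                      score = numeric(), categories = character())
    attr(out, "criteria") <- M
    attr(out, "terms") <- terms
    class(out) <- c("ndkg_ranking", "data.frame")
    return(out)
  }
  if (rescale) {
    fam <- ifelse(startsWith(colnames(M), "uni:"), "unigram",
                  ifelse(startsWith(colnames(M), "ent:BEHAVIOR:"), "behavior",
                         "entity"))
    for (f in unique(fam)) {
      blk <- M[, fam == f, drop = FALSE]
      rng <- range(blk)
      if (diff(rng) > 0) M[, fam == f] <- (blk - rng[1]) / diff(rng)
    }
  }
  w <- owa_weights(quantifier, ncol(M))
  scores <- apply(M, 1, function(v) owa_aggregate(w, v))
  doc_ids <- sub("^res:", "", rownames(M))
  ord <- order(-scores, doc_ids)
  ord <- ord[seq_len(min(top_n, length(ord)))]
  urls <- kg$nodes$url[match(rownames(M)[ord], kg$nodes$node_id)]
  cat_edges <- kg$edges[kg$edges$rel == "CONTAINS" &
                          startsWith(kg$edges$dst, "cat:"), , drop = FALSE]
  cats <- vapply(rownames(M)[ord], function(rid) {
    paste(sub("^cat:", "", cat_edges$dst[cat_edges$src == rid]), collapse = "|")
  }, character(1))
  out <- data.frame(doc_id = doc_ids[ord], url = urls, score = scores[ord],
                    categories = unname(cats), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "criteria") <- M[ord, , drop = FALSE]
  attr(out, "terms") <- terms
  class(out) <- c("ndkg_ranking", "data.frame")
  out
}
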