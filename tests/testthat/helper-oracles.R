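# Independent oracles and fixture builders shared across test files.
# Oracles are written against the contract, not against the package code
# paths they check.

# a token stream built directly from tokens (no preprocessing)
make_stream <- function(tokens, doc_id = "d1") {
  structure(list(doc_id = doc_id, tokens = tokens,
                 offsets = data.frame(start = seq_along(tokens),
                                      end = seq_along(tokens))),
            class = "ndkg_tokens")
}

# lemma-stable, non-stop pseudo tokens for random fixtures
token_pool <- c("zena", "zeno", "zima", "zolo", "muna", "mira", "pela",
                "pino", "rava", "ruko", "sela", "tovi", "vema", "bako")

# brute-force phrase matcher: enumerate every candidate n-gram match, then
# apply the longest-match, left-to-right, non-overlap rule
oracle_match <- function(tokens, pattern_keys, max_len) {
  cands <- list()
  n <- length(tokens)
  for (s in seq_len(n)) {
    for (L in seq_len(min(max_len, n - s + 1))) {
      key <- paste(tokens[s:(s + L - 1)], collapse = " ")
      if (key %in% pattern_keys) {
        cands[[length(cands) + 1]] <- list(start = s, len = L, key = key)
      }
    }
  }
  out <- list()
  p <- 1
  for (s in seq_len(n)) {
    if (s < p) next
    here <- Filter(function(c) c$start == s, cands)
    if (!length(here)) next
    best <- here[[which.max(vapply(here, `[[`, numeric(1), "len"))]]
    out[[length(out) + 1]] <- best
    p <- s + best$len
  }
  out
}

# a random (lexicon, stream) fixture for the NER property tests
random_ner_fixture <- function() {
  n_pat <- sample(2:6, 1)
  pats <- unique(replicate(n_pat, {
    paste(sample(token_pool, sample(1:3, 1), replace = TRUE), collapse = " ")
  }))
  entries <- data.frame(surface = pats, canonical = pats,
                        vocab = sample(c("HPO", "UMLS", "ERIC"), length(pats),
                                       replace = TRUE),
                        stringsAsFactors = FALSE)
  tokens <- sample(token_pool, sample(5:25, 1), replace = TRUE)
  list(entries = entries, tokens = tokens)
}

# independent macro-F1 via explicit confusion counts
oracle_macro_f1 <- function(pred, truth, categories) {
  total <- 0
  for (cc in categories) {
    tp <- fp <- fn <- 0
    for (i in seq_along(pred)) {
      p <- cc %in% pred[[i]]; t <- cc %in% truth[[i]]
      tp <- tp + (p && t); fp <- fp + (p && !t); fn <- fn + (!p && t)
    }
    total <- total + if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  total / length(categories)
}

# independent OWA: explicit sort and dot product
oracle_owa <- function(w, v) {
  vs <- sort(v, decreasing = TRUE)
  s <- 0
  for (i in seq_along(w)) s <- s + w[i] * vs[i]
  s
}

# small fixture graph with one entity vocabulary; edge weights returned
# for oracle use. Entities are single lemma-stable tokens.
random_fixture_graph <- function(n_res = sample(3:8, 1),
                                 n_ent = sample(2:5, 1)) {
  ents <- paste0("term", letters[seq_len(n_ent)], "o")
  doc_ids <- sprintf("fd%02d", seq_len(n_res))
  corpus <- data.frame(
    doc_id = doc_ids, url = paste0("https://x/", doc_ids),
    source = "other", parent_id = NA_character_,
    resource_type = "webpage", text = "placeholder",
    stringsAsFactors = FALSE)
  class(corpus) <- c("ndkg_corpus", "data.frame")
  rel <- do.call(rbind, lapply(doc_ids, function(d) {
    keep <- runif(n_ent) < 0.6
    if (!any(keep)) keep[sample.int(n_ent, 1)] <- TRUE
    data.frame(doc_id = d, canonical = ents[keep], vocab = "UMLS",
               tf = 1L, dl = sum(keep), weight = round(runif(sum(keep)), 3),
               stringsAsFactors = FALSE)
  }))
  kg <- build_graph(corpus, rel)
  entries <- data.frame(surface = ents, canonical = ents, vocab = "UMLS",
                        stringsAsFactors = FALSE)
  # entities with at least one edge (criteria with no node anywhere in
  # the graph are dropped from a query by contract)
  present <- intersect(ents, unique(rel$canonical))
  list(kg = kg, rel = rel, ents = present, doc_ids = doc_ids,
       lex = compile_lexicon(entries))
}

# synthetic labeled documents with deterministic per-category marker tokens
marker_labeled_set <- function(n, seed) {
  cats <- ndd_categories()
  markers <- paste0("marker", gsub("_", "", cats))
  with_seed <- function(s, code) { set.seed(s); code }
  with_seed(seed, {
    labels <- lapply(seq_len(n), function(i) {
      k <- sample(1:2, 1)
      sort(sample(cats, k))
    })
    texts <- vapply(seq_along(labels), function(i) {
      filler <- paste(sample(token_pool, 20, replace = TRUE), collapse = " ")
      paste(c(filler, rep(markers[match(labels[[i]], cats)], 3)), collapse = " ")
    }, character(1))
    labeled_set(texts, labels)
  })
}
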