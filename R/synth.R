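# Seeded synthetic fixtures for the whole pipeline: controlled-vocabulary
# lexicons with planted cross-vocabulary overlaps, an offline gazetteer of
# fictional places, a corpus with planted topic mixtures (disjoint topic
# vocabularies drawn through a Dirichlet), planted entity surface-form
# injections (pre-lemma, so the NER path is exercised end to end),
# category marker tokens, and postal codes; plus the planted ground truth
# for every document. Everything is regenerable bit-exactly from
# (config, seed).

#' Synthetic-data configuration
#'
#' Defaults describe the study conditions the tests run under: a few
#' hundred documents, three planted topics with disjoint vocabularies,
#' mean document length ~80 tokens (negative binomial), one expected
#' injection of each chosen entity per document, deterministic one-token
#' category markers, and a small pool of fictional cities.
#'
#' @param n_docs documents to generate.
#' @param n_topics_planted planted topics (disjoint vocabularies).
#' @param vocab_per_topic words per planted topic vocabulary.
#' @param n_entities_per_vocab entities per controlled vocabulary.
#' @param vocab_overlap canonical terms shared between vocabulary pairs
#'   (exercises IS_ASSOCIATED_WITH).
#' @param entity_injection_rate expected mentions per chosen entity per
#'   document (Poisson, shifted so chosen entities appear at least once).
#' @param entities_per_doc how many entities are chosen per document.
#' @param category_marker_map named character: category -> marker token.
#' @param location_pool data frame `city`, `province`, `prefix` of
#'   fictional places.
#' @param doc_length_mean,doc_length_size negative-binomial length model.
#' @param label_weights expected relative category frequencies (default
#'   mirrors a strongly skewed label distribution, services-heavy).
#' @param label_noise probability of flipping a document's planted label
#'   set to a random one (default 0).
#' @param topic_concentration Dirichlet concentration of planted mixtures
#'   (small = near-single-topic documents).
#' @param p_location probability a document carries a planted location.
#' @param p_behavior,p_age probability of a planted challenging-behavior
#'   phrase / age term per document.
#' @param marker_repeats how many times each planted label's marker token
#'   is appended (0 drops markers, e.g. for a pure topic-recovery corpus).
#' @param seed mandatory RNG seed.
#' @return list of class `ndkg_synth_config`.
#' @export
synth_config <- function(n_docs = 300, n_topics_planted = 3,
                         vocab_per_topic = 40, n_entities_per_vocab = 8,
                         vocab_overlap = 2, entity_injection_rate = 1,
                         entities_per_doc = 3,
                         category_marker_map = NULL, location_pool = NULL,
                         doc_length_mean = 80, doc_length_size = 10,
                         label_weights = c(financial_help = 116, education = 420,
                                           services = 1419, core_knowledge = 1024,
                                           other = 143),
                         label_noise = 0, topic_concentration = 0.1,
                         p_location = 0.3, p_behavior = 0.3, p_age = 0.3,
                         marker_repeats = 3, seed) {
  if (missing(seed)) stop_ndkg("synth_config requires an explicit seed")
  if (is.null(category_marker_map)) {
    category_marker_map <- stats::setNames(
      paste0("marker", gsub("_", "", ndd_categories())), ndd_categories())
  }
  if (is.null(location_pool)) {
    location_pool <- data.frame(
      city = c("Norvale", "Eastbrook", "Lakemount", "Westhollow"),
      province = c("Aspenia", "Aspenia", "Borealia", "Borealia"),
      prefix = c("T6G", "T2X", "V5K", "V8N"),
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(n_docs = n_docs, n_topics_planted = n_topics_planted,
         vocab_per_topic = vocab_per_topic,
         n_entities_per_vocab = n_entities_per_vocab,
         vocab_overlap = vocab_overlap,
         entity_injection_rate = entity_injection_rate,
         entities_per_doc = entities_per_doc,
         category_marker_map = category_marker_map,
         location_pool = location_pool,
         doc_length_mean = doc_length_mean, doc_length_size = doc_length_size,
         label_weights = label_weights, label_noise = label_noise,
         topic_concentration = topic_concentration,
         p_location = p_location, p_behavior = p_behavior, p_age = p_age,
         marker_repeats = marker_repeats, seed = seed),
    class = "ndkg_synth_config"
  )
}

# pronounceable pseudo-words, deterministic in the RNG state
.pseudo_words <- function(n, prefix = "") {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  made <- character(0)
  while (length(made) < n) {
    w <- paste0(prefix,
                paste0(sample(cons, 3, TRUE), sample(vow, 3, TRUE),
                       collapse = ""))
    made <- unique(c(made, w))
  }
  made[seq_len(n)]
}

#' Generate synthetic lexicons and gazetteer
#'
#' Builds HPO/UMLS/ERIC/AIRS vocabularies of pseudo-term entries with
#' `vocab_overlap` canonical terms shared between consecutive vocabulary
#' pairs, the ten challenging-behavior categories with two marker phrases
#' each, the three age terms, and a gazetteer covering the location pool
#' (postal prefixes and place names). Deterministic given the config seed.
#'
#' @param cfg an [synth_config()].
#' @param dir optional directory; when given, writes `lexicon.csv` and
#'   `gazetteer.csv`.
#' @return list with `lexicon` (data frame) and `gazetteer` (data frame).
#' @export
generate_lexicons <- function(cfg, dir = NULL) {
  res <- with_seed(cfg$seed + 1L, {
    vocabs <- c("HPO", "UMLS", "ERIC", "AIRS")
    n <- cfg$n_entities_per_vocab
    rows <- list()
    canon <- list()
    for (vi in seq_along(vocabs)) {
      canon[[vi]] <- .pseudo_words(n, prefix = tolower(substr(vocabs[vi], 1, 1)))
    }
    # planted overlaps: the first `vocab_overlap` canonical terms are
    # shared between the first two vocabularies (surfaces differ, as
    # synonyms would), exercising IS_ASSOCIATED_WITH
    if (cfg$vocab_overlap > 0) {
      k <- min(cfg$vocab_overlap, n)
      canon[[2]][seq_len(k)] <- canon[[1]][seq_len(k)]
    }
    for (vi in seq_along(vocabs)) {
      # vocabulary-specific surfaces (synonyms), so overlapping canonical
      # terms are still matched under one vocabulary at a time
      surf1 <- paste0(canon[[vi]], tolower(substr(vocabs[vi], 1, 1)))
      surf2 <- paste(surf1, "supports")   # plural; lemmatizes to "support"
      rows[[vi]] <- data.frame(
        surface = c(surf1, surf2),
        canonical = rep(canon[[vi]], 2),
        vocab = vocabs[vi],
        concept_id = rep(sprintf("%s:%04d", vocabs[vi], seq_len(n)), 2),
        behavior_category = NA_character_,
        stringsAsFactors = FALSE
      )
    }
    beh <- behavior_categories()
    beh_words <- .pseudo_words(length(beh), prefix = "x")
    rows$behavior <- data.frame(
      surface = c(beh, beh_words),
      canonical = c(beh, beh_words),
      vocab = "BEHAVIOR",
      concept_id = NA_character_,
      behavior_category = c(beh, beh),
      stringsAsFactors = FALSE
    )
    rows$age <- data.frame(
      surface = c("child", "children", "teen", "teenager", "adult", "adults"),
      canonical = c("child", "child", "teen", "teen", "adult", "adult"),
      vocab = "AGE", concept_id = NA_character_,
      behavior_category = NA_character_, stringsAsFactors = FALSE
    )
    lexicon <- do.call(rbind, unname(rows))
    lp <- cfg$location_pool
    gazetteer <- rbind(
      data.frame(kind = "postal_prefix", key = lp$prefix, city = lp$city,
                 province = lp$province, stringsAsFactors = FALSE),
      data.frame(kind = "name", key = lp$city, city = lp$city,
                 province = lp$province, stringsAsFactors = FALSE),
      data.frame(kind = "name", key = unique(lp$province), city = "",
                 province = unique(lp$province), stringsAsFactors = FALSE)
    )
    list(lexicon = lexicon, gazetteer = gazetteer)
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$lexicon, file.path(dir, "lexicon.csv"), row.names = FALSE)
    utils::write.csv(res$gazetteer, file.path(dir, "gazetteer.csv"), row.names = FALSE)
  }
  res
}

#' Generate a synthetic corpus with planted structure
#'
#' Each document draws a topic mixture from a Dirichlet over the planted
#' topics, samples body tokens from disjoint per-topic vocabularies,
#' injects entity surface forms (counts recorded as ground truth), appends
#' category marker tokens for its planted labels, and embeds a postal code
#' and/or city name for its planted location.
#'
#' @param cfg an [synth_config()].
#' @param lex output of [generate_lexicons()] (lexicon + gazetteer).
#' @param dir optional directory; when given, writes `corpus.jsonl` and
#'   `ground_truth.json`.
#' @return list with `corpus` (an `ndkg_corpus`) and `truth` (per-doc list
#'   of planted mixture, entity counts, labels, location).
#' @export
generate_corpus <- function(cfg, lex, dir = NULL) {
  res <- with_seed(cfg$seed + 2L, {
    K <- cfg$n_topics_planted
    topic_vocab <- lapply(seq_len(K), function(k) {
      .pseudo_words(cfg$vocab_per_topic, prefix = sprintf("t%d", k))
    })
    # Zipf-weighted planted topic-word distributions, so each planted
    # topic has a well-defined set of top words to recover
    zipf <- (1 / seq_len(cfg$vocab_per_topic))
    zipf <- zipf / sum(zipf)
    lexdf <- lex$lexicon
    ent_pool <- lexdf[lexdf$vocab %in% c("HPO", "UMLS", "ERIC", "AIRS"), ]
    cats <- ndd_categories()
    lw <- cfg$label_weights[cats] / sum(cfg$label_weights)
    lp <- cfg$location_pool
    docs <- vector("list", cfg$n_docs)
    truth <- vector("list", cfg$n_docs)
    for (i in seq_len(cfg$n_docs)) {
      mix <- as.numeric(stats::rgamma(K, cfg$topic_concentration))
      mix <- mix / sum(mix)
      len <- stats::rnbinom(1, size = cfg$doc_length_size,
                            mu = cfg$doc_length_mean) + 10
      zs <- tabulate(sample.int(K, len, replace = TRUE, prob = mix), K)
      body <- unlist(lapply(seq_len(K), function(k) {
        if (zs[k] == 0) character() else
          sample(topic_vocab[[k]], zs[k], replace = TRUE, prob = zipf)
      }))
      # entity injections: choose entities, inject surface forms
      picked <- ent_pool[sample.int(nrow(ent_pool), cfg$entities_per_doc), , drop = FALSE]
      counts <- if (nrow(picked))
        stats::rpois(nrow(picked), cfg$entity_injection_rate - 1) + 1 else integer()
      ent_tokens <- rep(picked$surface, counts)
      # occasional challenging-behavior phrase and age term
      beh_cat <- NA_character_; age <- NA_character_
      if (stats::runif(1) < cfg$p_behavior) {
        bpool <- lexdf[lexdf$vocab == "BEHAVIOR", ]
        brow <- bpool[sample.int(nrow(bpool), 1), ]
        beh_cat <- brow$behavior_category
        ent_tokens <- c(ent_tokens, brow$surface)
      }
      if (stats::runif(1) < cfg$p_age) {
        apool <- lexdf[lexdf$vocab == "AGE", ]
        arow <- apool[sample.int(nrow(apool), 1), ]
        age <- arow$canonical
        ent_tokens <- c(ent_tokens, arow$surface)
      }
      # labels: 1-2 categories drawn by the skewed profile
      n_lab <- 1 + stats::rbinom(1, 1, 0.3)
      labels <- unique(sample(cats, n_lab, prob = lw, replace = TRUE))
      markers <- rep(unname(cfg$category_marker_map[labels]),
                     each = cfg$marker_repeats)
      # location
      loc <- NULL
      loc_tokens <- character()
      if (stats::runif(1) < cfg$p_location) {
        loc <- lp[sample.int(nrow(lp), 1), ]
        code <- paste0(loc$prefix, " ", sample(0:9, 1),
                       sample(LETTERS, 1), sample(0:9, 1))
        loc_tokens <- c(code, loc$city)
      }
      pieces <- c(body, ent_tokens, markers, loc_tokens)
      text <- paste(sample(pieces), collapse = " ")
      doc_id <- sprintf("doc%04d", i)
      docs[[i]] <- list(doc_id = doc_id,
                        url = sprintf("https://example.org/%s", doc_id),
                        source = sample(c("caregiver", "inform_alberta"), 1),
                        text = text)
      ec <- tapply(counts, entity_key(picked$vocab, picked$canonical), sum)
      truth[[i]] <- list(
        mixture = mix,
        entity_counts = stats::setNames(as.integer(ec), names(ec)),
        labels = labels,
        behavior = beh_cat, age = age,
        city = if (is.null(loc)) NA_character_ else loc$city,
        province = if (is.null(loc)) NA_character_ else loc$province
      )
    }
    names(truth) <- vapply(docs, `[[`, character(1), "doc_id")
    corpus <- data.frame(
      doc_id = vapply(docs, `[[`, character(1), "doc_id"),
      url = vapply(docs, `[[`, character(1), "url"),
      source = vapply(docs, `[[`, character(1), "source"),
      parent_id = NA_character_,
      resource_type = "webpage",
      text = vapply(docs, `[[`, character(1), "text"),
      stringsAsFactors = FALSE
    )
    class(corpus) <- c("ndkg_corpus", "data.frame")
    list(corpus = corpus, truth = truth,
         topic_vocab = topic_vocab, topic_word_prob = zipf)
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    con <- file(file.path(dir, "corpus.jsonl"), "w", encoding = "UTF-8")
    for (i in seq_len(nrow(res$corpus))) {
      writeLines(jsonlite::toJSON(as.list(res$corpus[i, c("doc_id", "url", "source", "text")]),
                                  auto_unbox = TRUE), con)
    }
    close(con)
    jsonlite::write_json(res$truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  res
}

#' Emit the planted multilabel training set
#'
#' Writes/returns the planted label assignments, optionally perturbed by a
#' label-noise rate (a noisy document receives a fresh label set drawn
#' from the skewed profile).
#'
#' @param cfg an [synth_config()].
#' @param gen output of [generate_corpus()].
#' @param dir optional directory; writes `labels.csv` when given.
#' @return data frame `doc_id`, `labels` (pipe-separated).
#' @export
generate_labeled_set <- function(cfg, gen, dir = NULL) {
  labels <- lapply(gen$truth, `[[`, "labels")
  out <- with_seed(cfg$seed + 3L, {
    if (cfg$label_noise > 0) {
      cats <- ndd_categories()
      lw <- cfg$label_weights[cats] / sum(cfg$label_weights)
      flip <- stats::runif(length(labels)) < cfg$label_noise
      labels[flip] <- lapply(which(flip), function(i)
        unique(sample(cats, 1 + stats::rbinom(1, 1, 0.3), prob = lw, replace = TRUE)))
    }
    data.frame(doc_id = names(labels),
               labels = vapply(labels, paste, character(1), collapse = "|"),
               stringsAsFactors = FALSE)
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(dir, "labels.csv"), row.names = FALSE)
  }
  out
}

#' Generate every fixture in one call
#'
#' @param cfg an [synth_config()].
#' @param dir output directory (`corpus.jsonl`, `lexicon.csv`,
#'   `gazetteer.csv`, `labels.csv`, `ground_truth.json`).
#' @return list with `corpus`, `truth`, `lexicon`, `gazetteer`, `labels`,
#'   `topic_vocab`.
#' @export
generate_all <- function(cfg, dir = NULL) {
  lex <- generate_lexicons(cfg, dir)
  gen <- generate_corpus(cfg, lex, dir)
  lab <- generate_labeled_set(cfg, gen, dir)
  c(gen, lex, list(labels = lab))
}
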