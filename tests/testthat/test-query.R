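test_that("quantifier weights follow Q(i/n) - Q((i-1)/n) and sum to one", {
  expect_equal(owa_weights(rim_quantifier("identity"), 4), rep(0.25, 4))
  expect_equal(owa_weights(rim_quantifier("most", 0.3, 0.8), 5),
               c(0, 0.2, 0.4, 0.4, 0))
  expect_equal(owa_weights(rim_quantifier("all"), 5), c(0, 0, 0, 0, 1))
  expect_equal(owa_weights(rim_quantifier("at_least_n", n = 2), 4),
               c(0, 1, 0, 0))
  for (kind in c("most", "some", "all", "identity")) {
    for (n in 1:20) {
      w <- owa_weights(rim_quantifier(kind), n)
      expect_equal(sum(w), 1, tolerance = 1e-12)
      expect_true(all(w >= -1e-15))
    }
  }
  for (n in 1:20) {
    w <- owa_weights(rim_quantifier("at_least_n", n = 3), n)
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
})

test_that("OWA aggregation sorts descending and honours classic special cases", {
  expect_equal(owa_aggregate(rep(1 / 3, 3), c(0.2, 0.4, 0.6)), 0.4)
  expect_equal(owa_aggregate(c(1, 0, 0), c(0.3, 0.9, 0.1)), 0.9)  # max
  expect_equal(owa_aggregate(c(0, 0, 1), c(0.3, 0.9, 0.1)), 0.1)  # min
  expect_equal(owa_aggregate(c(0, 0.2, 0.4, 0.4, 0),
                             c(0.9, 0.5, 0.7, 0.1, 0.3)), 0.46)
  expect_error(owa_aggregate(c(0.5, 0.5), c(1, 2, 3)), "length mismatch")
})

test_that("OWA is bounded, monotone and idempotent", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(1:12, 1)
    q <- rim_quantifier(sample(c("most", "some", "all", "identity"), 1))
    w <- owa_weights(q, n)
    v <- runif(n)
    agg <- owa_aggregate(w, v)
    expect_gte(agg, min(v) - 1e-12)
    expect_lte(agg, max(v) + 1e-12)
    expect_equal(owa_aggregate(w, v), oracle_owa(w, v), tolerance = 1e-12)
    # monotonicity: bump one value
    i <- sample.int(n, 1)
    v2 <- v; v2[i] <- v2[i] + runif(1)
    expect_gte(owa_aggregate(w, v2), agg - 1e-12)
    # idempotence
    expect_equal(owa_aggregate(w, rep(0.37, n)), 0.37, tolerance = 1e-12)
  }
})

test_that("query parsing extracts entities, unigrams and the intent category", {
  lexf <- system.file("extdata", "synthetic_lexicon.csv", package = "ndkg")
  entries <- read_lexicon(lexf)
  lex <- compile_lexicon(entries)
  im <- intent_model_from_lexicon(entries)
  q <- parse_query("aggressive behavior and kicking and spitting",
                   lex, topic_vocab = c("aggressive", "behavior"), intent = im)
  expect_true("Spitting" %in% q$entities$canonical)
  expect_true("UMLS" %in% q$entities$vocab)
  expect_equal(q$behavior_category, "behavioral concerns")
  expect_setequal(q$unigrams, c("aggressive", "behavior"))
  # behavior phrases arrive collapsed onto their category
  expect_true("behavioral concerns" %in% q$entities$canonical)
  empty <- parse_query("", lex)
  expect_equal(nrow(empty$entities), 0)
  expect_length(empty$unigrams, 0)
  one <- parse_query("respite care", lex)
  expect_equal(one$entities$canonical, "respite care")
})

test_that("candidate retrieval fills one slot per criterion with edge weight or 0", {
  fx <- random_fixture_graph(n_res = 4, n_ent = 3)
  terms <- parse_query(paste(fx$ents, collapse = " "), fx$lex)
  M <- retrieve_candidates(fx$kg, terms)
  expect_equal(ncol(M), length(fx$ents))
  # every candidate row matches the relevance table exactly
  for (r in rownames(M)) {
    doc <- sub("^res:", "", r)
    for (cn in colnames(M)) {
      canon <- sub("^ent:UMLS:", "", cn)
      w <- fx$rel$weight[fx$rel$doc_id == doc & fx$rel$canonical == canon]
      expect_equal(unname(M[r, cn]), if (length(w)) w else 0)
    }
  }
  # candidates = docs adjacent to at least one criterion
  expect_setequal(rownames(M),
                  sprintf("res:%s", unique(fx$rel$doc_id)))
})

test_that("ranking equals exhaustive per-resource OWA scoring on random graphs", {
  set.seed(33)
  for (rep in 1:50) {
    fx <- random_fixture_graph()
    n_crit <- sample(seq_along(fx$ents), 1)
    crit <- sample(fx$ents, n_crit)
    q <- rim_quantifier("most")
    r <- rank_resources(fx$kg, paste(crit, collapse = " "), fx$lex,
                        quantifier = q, top_n = 100)
    # oracle: score every resource over the same criteria
    w <- owa_weights(q, n_crit)
    oracle <- vapply(fx$doc_ids, function(d) {
      v <- vapply(crit, function(cn) {
        x <- fx$rel$weight[fx$rel$doc_id == d & fx$rel$canonical == cn]
        if (length(x)) x else 0
      }, numeric(1))
      oracle_owa(w, v)
    }, numeric(1))
    oracle <- oracle[vapply(fx$doc_ids, function(d)
      any(fx$rel$doc_id == d & fx$rel$canonical %in% crit), logical(1))]
    ord <- order(-oracle, names(oracle))
    expect_equal(r$doc_id, names(oracle)[ord])
    expect_equal(r$score, unname(oracle[ord]), tolerance = 1e-12)
  }
})

test_that("single-criterion ranking reduces to edge-weight sorting, top_n caps rows", {
  fx <- random_fixture_graph(n_res = 8, n_ent = 2)
  cn <- fx$ents[1]
  r <- rank_resources(fx$kg, cn, fx$lex, top_n = 100)
  sub <- fx$rel[fx$rel$canonical == cn, ]
  ord <- order(-sub$weight, sub$doc_id)
  expect_equal(r$doc_id, sub$doc_id[ord])
  r10 <- rank_resources(fx$kg, paste(fx$ents, collapse = " "), fx$lex, top_n = 3)
  expect_lte(nrow(r10), 3)
  # identity quantifier ranks by mean edge weight
  ri <- rank_resources(fx$kg, paste(fx$ents, collapse = " "), fx$lex,
                       quantifier = rim_quantifier("identity"), top_n = 100)
  means <- vapply(ri$doc_id, function(d) {
    mean(vapply(fx$ents, function(e) {
      x <- fx$rel$weight[fx$rel$doc_id == d & fx$rel$canonical == e]
      if (length(x)) x else 0
    }, numeric(1)))
  }, numeric(1))
  expect_equal(ri$score, unname(means), tolerance = 1e-12)
  expect_true(all(diff(ri$score) <= 1e-12))
})
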