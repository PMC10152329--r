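test_that("count matrix uses frequency-ranked vocabulary with lexicographic ties", {
  streams <- list(make_stream(c("zena", "zena", "zolo"), "d1"),
                  make_stream(c("zolo", "muna"), "d2"))
  names(streams) <- c("d1", "d2")
  cm <- build_count_matrix(streams)
  expect_setequal(cm$vocab, c("zena", "zolo", "muna"))
  expect_equal(cm$counts["d1", "zena"], 2L)
  expect_equal(cm$counts["d2", "muna"], 1L)
  # totals: zena=2, zolo=2, muna=1 -> cap 2 keeps the tie broken by name
  cm2 <- build_count_matrix(streams, max_features = 2)
  expect_setequal(cm2$vocab, c("zena", "zolo"))
  # a doc with no in-vocabulary tokens keeps its zero row
  streams3 <- c(streams, list(d3 = make_stream("qqq", "d3")))
  cm3 <- build_count_matrix(streams3, max_features = 3)
  expect_equal(sum(cm3$counts["d3", ]), 0L)
  expect_error(build_count_matrix(list()), "empty")
})

test_that("LDA returns stochastic matrices, is seeded, and guards K", {
  set.seed(1)
  streams <- lapply(1:12, function(i) {
    make_stream(sample(token_pool[1:6], 30, replace = TRUE), sprintf("d%d", i))
  })
  names(streams) <- sprintf("d%d", 1:12)
  cm <- build_count_matrix(streams)
  m1 <- fit_lda(cm, 3, lda_config(seed = 4))
  expect_equal(rowSums(m1$theta), setNames(rep(1, 12), m1$docs), tolerance = 1e-6)
  expect_equal(unname(rowSums(m1$phi)), rep(1, 3), tolerance = 1e-6)
  expect_true(all(m1$theta >= 0) && all(m1$phi >= 0))
  m2 <- fit_lda(cm, 3, lda_config(seed = 4))
  expect_identical(m1$theta, m2$theta)
  expect_error(fit_lda(cm, 13, lda_config(seed = 1)), "exceeds")
  expect_error(fit_lda(cm, 1, lda_config(seed = 1)), ">= 2")
})

test_that("LDA recovers planted topics with disjoint vocabularies", {
  cfg <- synth_config(n_docs = 120, n_topics_planted = 2, vocab_per_topic = 25,
                      seed = 77)
  gen <- generate_corpus(cfg, generate_lexicons(cfg))
  streams <- preprocess_corpus(gen$corpus)
  m <- fit_lda(build_count_matrix(streams), 2, lda_config(seed = 3))
  tw <- top_words(m, 5)
  planted_prefix <- apply(tw, 1, function(ws) {
    pref <- substr(ws, 1, 2)
    length(unique(pref)) == 1 && all(pref %in% c("t1", "t2"))
  })
  expect_true(all(planted_prefix))
})

test_that("dominant topic is argmax with lowest-index ties", {
  expect_equal(dominant_topic(c(0.1, 0.7, 0.2)), 2L)
  expect_equal(dominant_topic(c(0.5, 0.5)), 1L)
  expect_equal(dominant_topic(rep(0.25, 4)), 1L)
  expect_equal(dominant_topic(rbind(c(0.9, 0.1), c(0.2, 0.8))), c(1L, 2L))
})

test_that("theta-phi product is exact and preserves row stochasticity", {
  # closed forms
  expect_equal(contains_ngram_weights(matrix(c(0.5, 0.5), 1),
                                      diag(2)), matrix(c(0.5, 0.5), 1))
  phi1 <- matrix(c(0.2, 0.3, 0.5), 1)
  expect_equal(contains_ngram_weights(matrix(1, 3, 1), phi1),
               matrix(rep(phi1, each = 3), 3))
  # random products against the double-loop oracle
  set.seed(5)
  for (rep in 1:20) {
    D <- sample(2:5, 1); K <- sample(2:4, 1); V <- sample(3:6, 1)
    theta <- matrix(rgamma(D * K, 1), D); theta <- theta / rowSums(theta)
    phi <- matrix(rgamma(K * V, 1), K); phi <- phi / rowSums(phi)
    got <- contains_ngram_weights(theta, phi)
    want <- matrix(0, D, V)
    for (d in 1:D) for (v in 1:V) for (k in 1:K) {
      want[d, v] <- want[d, v] + theta[d, k] * phi[k, v]
    }
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(unname(rowSums(got)), rep(1, D), tolerance = 1e-9)
  }
  expect_error(contains_ngram_weights(matrix(1, 2, 3), matrix(1, 2, 2)),
               "shape mismatch")
})

test_that("the topic hierarchy terminates and leaf docs partition the corpus", {
  set.seed(9)
  # small mixed corpus: immediate termination at threshold >= n
  streams <- lapply(1:10, function(i) {
    make_stream(sample(token_pool, 20, replace = TRUE), sprintf("d%d", i))
  })
  names(streams) <- sprintf("d%d", 1:10)
  root <- hierarchical_topic_model(streams, K0 = 3, threshold = 300,
                                   lda_config(seed = 2))
  lv <- leaf_topics(root)
  expect_equal(length(lv), 3)   # depth-1: every root topic is a leaf
  docs <- unlist(lapply(lv, `[[`, "doc_ids"))
  expect_equal(anyDuplicated(docs), 0)
  expect_setequal(docs, names(streams))

  # identical documents: the no-progress rule must stop the recursion
  ident <- lapply(sprintf("i%02d", 1:40), function(id)
    make_stream(rep(c("zena", "zolo", "muna"), 5), id))
  names(ident) <- sprintf("i%02d", 1:40)
  root2 <- hierarchical_topic_model(ident, K0 = 2, threshold = 10,
                                    lda_config(seed = 3))
  lv2 <- leaf_topics(root2)
  flagged <- vapply(lv2, function(l) l$no_progress || l$capped, logical(1))
  sizes <- vapply(lv2, function(l) length(l$doc_ids), integer(1))
  expect_true(all(sizes <= 10 | flagged))
  expect_setequal(unlist(lapply(lv2, `[[`, "doc_ids")), names(ident))

  # a two-level hierarchy has (K0 - recursed) + sum(child leaves) leaves
  n_nodes <- length(htm_nodes(root2))
  expect_equal(length(lv2),
               sum(vapply(htm_nodes(root2), function(nd) sum(nd$is_leaf_topic),
                          integer(1))))
  expect_gte(n_nodes, 1)
})
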