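simple_lexicon <- function() {
  data.frame(
    surface = c("autism spectrum disorder", "autism", "Sleep Issues"),
    canonical = c("autism spectrum disorder", "autism", "sleep issues"),
    vocab = c("HPO", "HPO", "BEHAVIOR"),
    behavior_category = c(NA, NA, "sleep issues"),
    stringsAsFactors = FALSE
  )
}

test_that("lexicon compilation lemmatizes surfaces like documents", {
  lex <- compile_lexicon(simple_lexicon())
  expect_setequal(names(lex$patterns),
                  c("autism spectrum disorder", "autism", "sleep issue"))
  expect_equal(lex$max_pattern_length, 3)
  # a surface made of stop words reduces to nothing and is dropped
  entries <- rbind(simple_lexicon(),
                   data.frame(surface = "the", canonical = "the",
                              vocab = "ERIC", behavior_category = NA))
  expect_warning(lex2 <- compile_lexicon(entries), "empty token sequence")
  expect_length(lex2$patterns, 3)
  # behavior_category is mandatory exactly for BEHAVIOR rows
  bad <- simple_lexicon(); bad$behavior_category[3] <- NA
  expect_error(compile_lexicon(bad), "behavior_category")
})

test_that("matching is longest-first, left-to-right, non-overlapping", {
  lex <- compile_lexicon(simple_lexicon())
  ts <- make_stream(c("autism", "spectrum", "disorder", "support"))
  m <- match_entities(ts, lex)
  expect_equal(nrow(m), 1)
  expect_equal(m$canonical, "autism spectrum disorder")
  expect_equal(c(m$start, m$end), c(1L, 4L))
  # empty stream
  expect_equal(nrow(match_entities(make_stream(character()), lex)), 0)
  # colliding patterns emit all entries at the same span
  coll <- data.frame(surface = c("autism", "autism"),
                     canonical = c("autism", "Autism"),
                     vocab = c("HPO", "UMLS"), stringsAsFactors = FALSE)
  m2 <- match_entities(make_stream("autism"), compile_lexicon(coll))
  expect_equal(nrow(m2), 2)
  expect_setequal(m2$vocab, c("HPO", "UMLS"))
})

test_that("matcher equals the exhaustive n-gram oracle on random fixtures", {
  set.seed(101)
  for (rep in 1:60) {
    fx <- random_ner_fixture()
    lex <- compile_lexicon(fx$entries)
    got <- match_entities(make_stream(fx$tokens), lex)
    want <- oracle_match(fx$tokens, names(lex$patterns), lex$max_pattern_length)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$start, vapply(want, `[[`, numeric(1), "start"))
      expect_equal(got$end - got$start, vapply(want, `[[`, numeric(1), "len"))
    }
  }
})

test_that("frequency counting and distinct-entity bookkeeping", {
  m <- data.frame(
    doc_id = c("d1", "d1", "d1"),
    canonical = c("autism", "autism", "community"),
    vocab = c("HPO", "HPO", "ERIC"),
    concept_id = NA, behavior_category = NA,
    start = 1:3, end = 2:4, stringsAsFactors = FALSE
  )
  freq <- count_frequencies(m, doc_ids = c("d1", "d2"))
  expect_equal(freq$tf$tf[freq$tf$canonical == "autism"], 2L)
  expect_equal(freq$tf$tf[freq$tf$canonical == "community"], 1L)
  expect_equal(unname(freq$distinct_entities), c(2L, 0L))
  # total mentions are conserved
  expect_equal(sum(freq$tf$tf), nrow(m))
})

test_that("co-occurrence counts are document-level, symmetric and bounded", {
  m <- data.frame(
    doc_id = c("d1", "d1", "d2", "d2", "d3"),
    canonical = c("a", "b", "a", "b", "a"),
    vocab = "UMLS", concept_id = NA, behavior_category = NA,
    start = 1, end = 2, stringsAsFactors = FALSE
  )
  co <- cooccurrences(m)
  expect_equal(nrow(co), 1)
  expect_equal(co$count, 2L)      # both in d1 and d2; d3 has a alone
  expect_true(co$a < co$b)        # unordered key stored once
  # single-entity corpus
  expect_equal(nrow(cooccurrences(m[5, ])), 0)
  # upper-bound invariant on random fixtures
  set.seed(7)
  for (rep in 1:20) {
    nm <- sample(20:60, 1)
    mm <- data.frame(
      doc_id = sample(sprintf("d%d", 1:6), nm, replace = TRUE),
      canonical = sample(letters[1:5], nm, replace = TRUE),
      vocab = "HPO", concept_id = NA, behavior_category = NA,
      start = 1, end = 2, stringsAsFactors = FALSE
    )
    co <- cooccurrences(mm)
    df <- table(unique(mm[c("doc_id", "canonical")])$canonical)
    for (i in seq_len(nrow(co))) {
      ka <- sub("^HPO:", "", co$a[i]); kb <- sub("^HPO:", "", co$b[i])
      expect_lte(co$count[i], min(df[ka], df[kb]))
    }
  }
})
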