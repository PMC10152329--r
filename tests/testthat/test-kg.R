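tiny_corpus <- function(n = 1) {
  ids <- sprintf("d%d", seq_len(n))
  df <- data.frame(doc_id = ids, url = paste0("https://x/", ids),
                   source = "other", parent_id = NA_character_,
                   resource_type = "webpage", text = "t",
                   stringsAsFactors = FALSE)
  class(df) <- c("ndkg_corpus", "data.frame")
  df
}

test_that("CONTAINS weights carry the pivoted-normalization relevance", {
  # tf=2, dl=1, pivot=1, slope=0.2 -> (1 + log 2) / (0.8*1 + 0.2*1)
  p <- relevance_params(slope = 0.2, pivot = 1)
  rel <- data.frame(doc_id = "d1", canonical = "autism", vocab = "HPO",
                    tf = 2L, dl = 1L,
                    weight = entity_relevance(2, 1, p))
  kg <- build_graph(tiny_corpus(1), rel)
  e <- kg$edges[kg$edges$rel == "CONTAINS", ]
  expect_equal(nrow(e), 1)
  expect_equal(e$weight, (1 + log(2)) / 1)
  expect_equal(kg$nodes$node_type, c("Resource", "HPO"))
})

test_that("shared canonical terms across vocabularies get IS_ASSOCIATED_WITH", {
  rel <- data.frame(doc_id = c("d1", "d1", "d2"),
                    canonical = c("autism", "autism", "autism"),
                    vocab = c("HPO", "ERIC", "ERIC"),
                    tf = 1L, dl = 1L, weight = 1)
  kg <- build_graph(tiny_corpus(2), rel)
  a <- kg$edges[kg$edges$rel == "IS_ASSOCIATED_WITH", ]
  expect_equal(nrow(a), 1)
  # detected together in d1 only
  expect_equal(a$weight, 1)
  expect_setequal(c(a$src, a$dst), c("ent:ERIC:autism", "ent:HPO:autism"))
})

test_that("graph counts equal brute-force enumeration on a synthetic fixture", {
  cfg <- synth_config(n_docs = 25, seed = 55)
  all <- generate_all(cfg)
  stops <- ndkg_stopwords()
  streams <- preprocess_corpus(all$corpus, stops)
  lex <- compile_lexicon(all$lexicon, stops)
  mentions <- collapse_behavior(match_corpus(streams, lex))
  freq <- count_frequencies(mentions, all$corpus$doc_id)
  p <- relevance_params(pivot = compute_pivot(freq))
  rel <- relevance_scores(freq, p)
  cooc <- cooccurrences(mentions)
  kg <- build_graph(all$corpus, rel, cooc)
  # nodes: one resource per doc + one per distinct (vocab, canonical)
  expect_equal(sum(kg$nodes$node_type == "Resource"), nrow(all$corpus))
  expect_equal(nrow(kg$nodes),
               nrow(all$corpus) + nrow(unique(rel[c("vocab", "canonical")])))
  # edges: CONTAINS = relevance rows; OCCURRED_TOGETHER = cooc rows
  expect_equal(sum(kg$edges$rel == "CONTAINS"), nrow(rel))
  expect_equal(sum(kg$edges$rel == "OCCURRED_TOGETHER"), nrow(cooc))
  # planted entity counts round-trip through the NER path
  for (doc in names(all$truth)[1:10]) {
    tfm <- freq$tf[freq$tf$doc_id == doc, ]
    got <- setNames(tfm$tf, entity_key(tfm$vocab, tfm$canonical))
    planted <- all$truth[[doc]]$entity_counts
    expect_equal(unname(got[names(planted)]), unname(planted))
  }
  expect_length(validate_schema(kg), 0)
})

test_that("schema validation flags weight and endpoint violations", {
  rel <- data.frame(doc_id = "d1", canonical = "a", vocab = "HPO",
                    tf = 1L, dl = 1L, weight = 0.5)
  kg <- build_graph(tiny_corpus(1), rel)
  expect_length(validate_schema(kg), 0)
  bad1 <- kg
  bad1$edges$weight[1] <- NA
  expect_match(validate_schema(bad1), "missing weight")
  bad2 <- kg
  bad2$edges$src[1] <- bad2$edges$dst[1]   # HPO -> HPO under CONTAINS
  expect_match(validate_schema(bad2), "illegal endpoints")
  bad3 <- kg
  bad3$edges <- rbind(bad3$edges,
                      data.frame(src = "res:d1", rel = "belongsToTopic",
                                 dst = "ent:HPO:a", weight = 0.2))
  expect_match(validate_schema(bad3), "illegal endpoints")
  bad4 <- kg
  bad4$edges$dst[1] <- "ent:HPO:missing"
  expect_match(validate_schema(bad4), "dangling")
})

test_that("a built graph validates and exports round-trip exactly", {
  cfg <- synth_config(n_docs = 30, seed = 91)
  all <- generate_all(cfg)
  gazf <- withr::local_tempfile(fileext = ".csv")
  write.csv(all$gazetteer, gazf, row.names = FALSE)
  lab <- labeled_set(all$corpus$text[match(all$labels$doc_id, all$corpus$doc_id)],
                     strsplit(all$labels$labels, "|", fixed = TRUE),
                     all$labels$doc_id)
  ann <- suppressWarnings(
    annotate_corpus(all$corpus, all$lexicon,
                    gazetteer = read_gazetteer(gazf), labels = lab,
                    K0 = 3, threshold = 300,
                    lda_cfg = lda_config(seed = 6),
                    clf_cfg = classifier_config(seed = 6, epochs = 8)))
  kg <- ann$graph
  expect_length(validate_schema(kg), 0)
  # per-document location weights sum to 1 per place type
  for (lw in ann$locations) {
    if (length(lw$city)) expect_equal(sum(lw$city), 1)
    if (length(lw$province)) expect_equal(sum(lw$province), 1)
  }
  # a city edge implies the corresponding inProvince edge
  city_edges <- kg$edges[kg$edges$rel == "isLocatedIn" &
                           startsWith(kg$edges$dst, "city:"), ]
  inprov <- kg$edges[kg$edges$rel == "inProvince", ]
  expect_true(all(city_edges$dst %in% inprov$src))
  # csv_bulk round trip: node and edge multisets and weights exact
  out <- withr::local_tempdir()
  files <- export_graph(kg, out, "csv_bulk")
  expect_equal(length(grep("nodes_", list.files(out))),
               length(unique(kg$nodes$node_type)))
  expect_equal(length(grep("edges_", list.files(out))),
               length(unique(kg$edges$rel)))
  kg2 <- import_graph_csv(out)
  key <- function(g) {
    n <- g$nodes[order(g$nodes$node_id), ]
    e <- g$edges[order(g$edges$src, g$edges$rel, g$edges$dst), ]
    rownames(n) <- rownames(e) <- NULL
    list(n = n, e = e)
  }
  k1 <- key(kg); k2 <- key(kg2)
  expect_equal(k2$n[c("node_id", "node_type")], k1$n[c("node_id", "node_type")])
  expect_equal(k2$e$weight, k1$e$weight)   # exact, not approximate
  expect_identical(k2$e[c("src", "rel", "dst")], k1$e[c("src", "rel", "dst")])
})

test_that("N-Triples output parses with a standard RDF parser", {
  rel <- data.frame(doc_id = c("d1", "d2"), canonical = "a", vocab = "HPO",
                    tf = 1L, dl = 1L, weight = c(0.5, 0.25))
  kg <- build_graph(tiny_corpus(2), rel)
  out <- withr::local_tempdir()
  f <- export_graph(kg, out, "ntriples")
  res <- system2(Sys.which("python"), c("-c", shQuote(paste0(
    "import rdflib,sys; g=rdflib.Graph(); g.parse('", f,
    "', format='nt'); print(len(g))"))), stdout = TRUE)
  expect_gt(as.integer(res[length(res)]), 0)
})

test_that("GraphML export reloads with matching node and edge counts", {
  rel <- data.frame(doc_id = "d1", canonical = "a", vocab = "HPO",
                    tf = 1L, dl = 1L, weight = 0.5)
  kg <- build_graph(tiny_corpus(1), rel)
  out <- withr::local_tempdir()
  f <- export_graph(kg, out, "graphml")
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(kg$nodes))
  expect_equal(igraph::ecount(g), nrow(kg$edges))
})
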