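test_that("macro F1 matches hand-computed confusion counts", {
  cats <- c("A", "B")
  pred <- list(c("A", "B"), "A", character(0))
  truth <- list(c("A", "B"), "B", "B")
  # A: TP=2? doc1 A yes; doc2 pred A truth no -> FP; doc3 none.
  # A: TP=1 FP=1 FN=0 -> F1 = 2/3 ; B: TP=1 FP=0 FN=2 -> F1 = 0.5
  expect_equal(macro_f1(pred, truth, cats), mean(c(2 / 3, 0.5)))
  expect_equal(macro_f1(truth, truth, cats), 1)
  empty <- list(character(0), character(0), character(0))
  expect_equal(macro_f1(empty, truth, cats), 0)
  # permutation invariance and oracle equivalence on random label sets
  set.seed(3)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    rnd <- function() lapply(seq_len(n), function(i)
      sample(ndd_categories(), sample(0:3, 1)))
    p <- rnd(); t <- rnd()
    expect_equal(macro_f1(p, t), oracle_macro_f1(p, t, ndd_categories()))
    perm <- sample(n)
    expect_equal(macro_f1(p[perm], t[perm]), macro_f1(p, t))
  }
})

test_that("stratified splits have exact sizes for single-label data and are seeded", {
  set.seed(8)
  labels <- lapply(1:100, function(i) sample(ndd_categories()[1:4], 1))
  ls <- labeled_set(rep("text body here", 100), labels)
  sp <- split_dataset(ls, seed = 5)
  expect_equal(length(sp$train$texts), 80)
  expect_equal(length(sp$val$texts), 10)
  expect_equal(length(sp$test$texts), 10)
  expect_setequal(c(sp$train$doc_ids, sp$val$doc_ids, sp$test$doc_ids),
                  ls$doc_ids)
  sp2 <- split_dataset(ls, seed = 5)
  expect_identical(sp$train$doc_ids, sp2$train$doc_ids)
  expect_false(identical(split_dataset(ls, seed = 6)$train$doc_ids,
                         sp$train$doc_ids))
  # a tiny category is still represented in training
  labels2 <- c(lapply(1:95, function(i) "services"), as.list(rep("other", 5)))
  ls2 <- labeled_set(rep("x y z", 100), labels2)
  sp3 <- split_dataset(ls2, seed = 1)
  expect_gte(sum(vapply(sp3$train$labels, function(l) "other" %in% l,
                        logical(1))), 1)
  expect_warning(
    split_dataset(labeled_set(rep("t", 4),
                              list("other", "services", "services", "services"))),
    "fewer than 3")
})

test_that("training on separable marker data reaches high validation F1, reproducibly", {
  ls <- marker_labeled_set(300, seed = 41)
  sp <- split_dataset(ls, seed = 2)
  m <- train_multilabel(sp$train, sp$val, classifier_config(seed = 7))
  expect_gte(max(m$val_history), 0.9)
  th <- select_threshold(m, sp$val)
  pred <- lapply(sp$test$texts, function(t) {
    p <- predict_proba(m, t)[1, ]
    m$categories[p > as.numeric(th)]
  })
  expect_gte(macro_f1(pred, sp$test$labels), 0.9)
  # bit-reproducible with the linear backbone
  m2 <- train_multilabel(sp$train, sp$val, classifier_config(seed = 7))
  expect_identical(m$W, m2$W)
  expect_identical(m$val_history, m2$val_history)
  expect_error(train_multilabel(sp$train, sp$val,
                                classifier_config(epochs = 0)), "epochs")
  expect_error(train_multilabel(sp$train, sp$val,
                                classifier_config(backbone = "transformer")),
               "runtime")
})

test_that("threshold selection searches exactly the 11-point grid", {
  ls <- marker_labeled_set(120, seed = 13)
  sp <- split_dataset(ls, seed = 3)
  m <- train_multilabel(sp$train, sp$val, classifier_config(seed = 1))
  th <- select_threshold(m, sp$val)
  grid <- attr(th, "grid")
  expect_equal(grid$threshold, seq(0, 1, by = 0.1))
  expect_equal(nrow(grid), 11)
  # the returned threshold attains the brute-force grid maximum
  P <- predict_proba(m, sp$val$texts)
  brute <- vapply(grid$threshold, function(t0) {
    pred <- apply(P, 1, function(p) m$categories[p > t0], simplify = FALSE)
    macro_f1(pred, sp$val$labels)
  }, numeric(1))
  expect_equal(grid$macro_f1, brute)
  expect_equal(as.numeric(th), grid$threshold[which.max(brute)])
  # a scorer pinned at probability 1.0 ties all thresholds below 1 -> 0.0
  sat <- m
  sat$W[] <- 0
  sat$b[] <- 1e6
  expect_equal(as.numeric(select_threshold(sat, sp$val)), 0)
})

test_that("thresholded membership prediction", {
  ls <- marker_labeled_set(60, seed = 19)
  m <- train_multilabel(ls, ls, classifier_config(seed = 1, epochs = 5))
  m$W[] <- 0
  m$b <- stats::qlogis(c(0.9, 0.2, 0.8, 0.1, 0.05))
  m$threshold <- 0.5
  expect_equal(predict_categories(m, "anything"),
               c("financial_help", "services"))
  m$threshold <- 1
  expect_length(predict_categories(m, "anything"), 0)
  m$threshold <- 0
  expect_length(predict_categories(m, "anything"), 5)
})

test_that("intent classification picks the planted category and breaks ties low", {
  # deterministic marker fixture
  cats <- behavior_categories()
  texts <- rep(paste0("sig", seq_along(cats)), each = 3)
  labels <- rep(cats, each = 3)
  m <- train_intent(texts, labels)
  expect_equal(classify_intent(m, "sig1 something"), "sleep issues")
  expect_equal(classify_intent(m, "about sig7 here"), "adaptive behavior")
  # uniform scorer falls back to the first category
  u <- intent_model(function(text) rep(1, 10))
  expect_equal(classify_intent(u, "whatever"), cats[1])
  # bundled synthetic lexicon: a verbose aggression query maps to
  # behavioral concerns
  lexf <- system.file("extdata", "synthetic_lexicon.csv", package = "ndkg")
  im <- intent_model_from_lexicon(read_lexicon(lexf))
  expect_equal(classify_intent(im, "my child hits other children at school"),
               "behavioral concerns")
})
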