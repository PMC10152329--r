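# Multilabel resource classification (5 categories, sigmoid outputs,
# validation-epoch selection, 11-point macro-F1 threshold grid) and the
# 10-way challenging-behavior intent classifier used on queries.
#
# The reference backbone is a linear bag-of-words scorer with one sigmoid
# per category: the protocol being exercised -- multilabel head, epoch
# selection on validation macro F1, threshold grid search -- is
# backbone-independent, and the linear model is bit-reproducible on one
# CPU. The transformer fine-tuning recipe (MiniLM-class encoder, dropout
# 0.3, AdamW with lr 3e-4 warm-up/cosine decay, beta = (0.9, 0.95),
# eps 1e-8, weight decay 0.01, batch 64, gradient clipping at 1.0, 20
# epochs, binary cross-entropy) is carried in the config for deployments
# with a deep-learning runtime.

#' The five resource categories
#' @return character vector, fixed order.
#' @export
ndd_categories <- function() {
  c("financial_help", "education", "services", "core_knowledge", "other")
}

#' The ten challenging-behavior categories
#' @return character vector, fixed order.
#' @export
behavior_categories <- function() {
  c("sleep issues", "sensory issues", "hyperactivity", "inattention",
    "repetitive behavior", "speech and language development",
    "adaptive behavior", "cognitive development", "social skills",
    "behavioral concerns")
}

#' Classifier configuration
#'
#' @param backbone `"linear_bow"` (reference, implemented here) or
#'   `"transformer"` (configuration carrier; requires an external
#'   deep-learning runtime).
#' @param dropout,lr,beta1,beta2,eps,weight_decay,batch_size,grad_clip_norm
#'   transformer fine-tuning hyperparameters (defaults as listed).
#' @param epochs training epochs (validation is scored after each).
#' @param loss `"bce"` (binary cross entropy).
#' @param lr_linear step size of the linear bag-of-words backbone.
#' @param seed RNG seed (epoch shuffling).
#' @return list of class `ndkg_clf_config`.
#' @export
classifier_config <- function(backbone = c("linear_bow", "transformer"),
                              dropout = 0.3, lr = 3e-4, beta1 = 0.9,
                              beta2 = 0.95, eps = 1e-8, weight_decay = 0.01,
                              batch_size = 64, grad_clip_norm = 1.0,
                              epochs = 20, loss = "bce", lr_linear = 4,
                              seed = 1) {
  backbone <- match.arg(backbone)
  structure(
    list(backbone = backbone, dropout = dropout, lr = lr, beta1 = beta1,
         beta2 = beta2, eps = eps, weight_decay = weight_decay,
         batch_size = batch_size, grad_clip_norm = grad_clip_norm,
         epochs = epochs, loss = loss, lr_linear = lr_linear, seed = seed),
    class = "ndkg_clf_config"
  )
}

#' Assemble a labeled document set
#'
#' @param texts character vector of document texts.
#' @param labels list of character vectors (each a non-empty subset of
#'   [ndd_categories()]), same length as `texts`.
#' @param doc_ids optional ids.
#' @return list of class `ndkg_labeled`.
#' @export
labeled_set <- function(texts, labels, doc_ids = NULL) {
  stopifnot(length(texts) == length(labels))
  bad <- !vapply(labels, function(l) length(l) > 0 && all(l %in% ndd_categories()), logical(1))
  if (any(bad)) stop_ndkg(sum(bad), " document(s) with empty or unknown labels")
  if (is.null(doc_ids)) doc_ids <- sprintf("d%d", seq_along(texts))
  structure(list(doc_ids = doc_ids, texts = texts, labels = labels),
            class = "ndkg_labeled")
}

#' Read a labels CSV (doc_id, pipe-separated labels)
#'
#' @param path CSV with columns `doc_id` and `labels` (e.g. `services|education`).
#' @param corpus an `ndkg_corpus` providing the texts.
#' @return an `ndkg_labeled` set restricted to documents present in the corpus.
#' @export
read_labels <- function(path, corpus) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  keep <- df$doc_id %in% corpus$doc_id
  df <- df[keep, , drop = FALSE]
  labeled_set(corpus$text[match(df$doc_id, corpus$doc_id)],
              strsplit(df$labels, "|", fixed = TRUE),
              doc_ids = df$doc_id)
}

.subset_labeled <- function(ls, idx) {
  labeled_set(ls$texts[idx], ls$labels[idx], ls$doc_ids[idx])
}

#' Stratified train/validation/test split
#'
#' Iterative stratification for multilabel data: documents are assigned
#' label by label (rarest label first) to the split with the greatest
#' remaining demand for that label, so per-category proportions are
#' preserved where possible. Deterministic given `seed`.
#'
#' @param labeled an `ndkg_labeled` set.
#' @param ratios three ratios summing to 1 (default 0.8/0.1/0.1).
#' @param seed RNG seed for the initial document shuffle.
#' @return list with `ndkg_labeled` elements `train`, `val`, `test`.
#' @export
split_dataset <- function(labeled, ratios = c(0.8, 0.1, 0.1), seed = 1) {
  stopifnot(abs(sum(ratios) - 1) < 1e-9, length(ratios) == 3)
  n <- length(labeled$texts)
  cats <- sort(unique(unlist(labeled$labels)))
  small <- cats[vapply(cats, function(cc)
    sum(vapply(labeled$labels, function(l) cc %in% l, logical(1))), integer(1)) < 3]
  if (length(small)) {
    warning("categor(ies) with fewer than 3 members: ",
            paste(small, collapse = ", "), "; best-effort placement",
            call. = FALSE)
  }
  ord <- with_seed(seed, sample.int(n))
  # hard integer split capacities (largest-remainder allocation), so the
  # overall sizes are exact; per-label demand is real-valued best-effort
  cap <- floor(ratios * n)
  rem <- ratios * n - cap
  short <- n - sum(cap)
  if (short > 0) {
    bump <- order(-rem)[seq_len(short)]
    cap[bump] <- cap[bump] + 1
  }
  demand <- sapply(cats, function(cc) {
    ratios * sum(vapply(labeled$labels, function(l) cc %in% l, logical(1)))
  })  # 3 x |cats|
  demand <- matrix(demand, nrow = 3, dimnames = list(NULL, cats))
  assignment <- integer(n)
  unassigned <- ord
  while (length(unassigned)) {
    counts <- vapply(cats, function(cc)
      sum(vapply(labeled$labels[unassigned], function(l) cc %in% l, logical(1))),
      integer(1))
    counts[counts == 0] <- NA
    if (all(is.na(counts))) break
    lab <- cats[which.min(counts)]
    docs <- unassigned[vapply(labeled$labels[unassigned],
                              function(l) lab %in% l, logical(1))]
    for (d in docs) {
      j <- .pick_split(demand[, lab], cap)
      assignment[d] <- j
      for (l2 in labeled$labels[[d]]) demand[j, l2] <- demand[j, l2] - 1
      cap[j] <- cap[j] - 1
    }
    unassigned <- setdiff(unassigned, docs)
  }
  for (d in unassigned) {     # label-less stragglers (not expected)
    j <- which.max(cap)
    assignment[d] <- j
    cap[j] <- cap[j] - 1
  }
  list(train = .subset_labeled(labeled, which(assignment == 1)),
       val = .subset_labeled(labeled, which(assignment == 2)),
       test = .subset_labeled(labeled, which(assignment == 3)))
}

.pick_split <- function(dem, cap) {
  open <- which(cap > 0)
  best <- open[dem[open] == max(dem[open])]
  if (length(best) > 1) best <- best[cap[best] == max(cap[best])]
  best[1]
}

#' Macro-averaged F1 for multilabel predictions
#'
#' Unweighted mean of per-category F1. A category with zero true and zero
#' predicted positives contributes F1 = 0 (conservative, deterministic).
#'
#' @param pred list of predicted label sets (character vectors; may be empty).
#' @param truth list of true label sets, aligned with `pred`.
#' @param categories category order (default [ndd_categories()]).
#' @return scalar in [0, 1].
#' @export
macro_f1 <- function(pred, truth, categories = ndd_categories()) {
  stopifnot(length(pred) == length(truth))
  f1s <- vapply(categories, function(cc) {
    p <- vapply(pred, function(l) cc %in% l, logical(1))
    t <- vapply(truth, function(l) cc %in% l, logical(1))
    tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1s)
}

# --- linear bag-of-words machinery ------------------------------------

.bow_vocab <- function(texts, stops, min_count = 1) {
  toks <- lapply(texts, function(t) preprocess(t, stops)$tokens)
  tab <- table(unlist(toks, use.names = FALSE))
  sort(names(tab)[tab >= min_count])
}

.bow_features <- function(texts, vocab, stops) {
  X <- matrix(0, length(texts), length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(texts)) {
    tt <- table(preprocess(texts[i], stops)$tokens)
    tt <- tt[names(tt) %in% vocab]
    if (length(tt)) X[i, names(tt)] <- log1p(as.numeric(tt))
  }
  X
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train the multilabel resource classifier
#'
#' Trains for `cfg$epochs` epochs, scoring validation macro F1 at threshold
#' 0.5 after each epoch, and returns the best-epoch checkpoint (ties go to
#' the earlier epoch). The epoch is selected first; the decision threshold
#' is tuned afterwards with [select_threshold()]. With the `linear_bow`
#' backbone (mini-batch gradient descent on binary cross entropy, zero
#' initialization, seeded shuffling) the whole path is bit-reproducible.
#'
#' @param train,val `ndkg_labeled` sets.
#' @param cfg an [classifier_config()].
#' @param stops stop list for featurization.
#' @return object of class `ndkg_multilabel`: weights, vocabulary,
#'   `threshold` (0.5 until tuned), `categories`, `config`, `val_history`.
#' @export
train_multilabel <- function(train, val, cfg = classifier_config(),
                             stops = ndkg_stopwords()) {
  if (cfg$backbone == "transformer") {
    stop_ndkg("the transformer backbone requires an external deep-learning ",
              "runtime; use backbone = 'linear_bow'")
  }
  if (cfg$epochs < 1) stop_ndkg("epochs must be >= 1 (no checkpoint otherwise)")
  if (!length(train$texts) || !length(val$texts)) {
    stop_ndkg("train and val must be non-empty")
  }
  if (length(unique(vapply(train$labels, paste, character(1), collapse = "|"))) == 1) {
    warning("degenerate training set: every document has the same label set",
            call. = FALSE)
  }
  cats <- ndd_categories()
  vocab <- .bow_vocab(train$texts, stops)
  X <- .bow_features(train$texts, vocab, stops)
  Y <- t(vapply(train$labels, function(l) as.numeric(cats %in% l),
                numeric(length(cats))))
  n <- nrow(X)
  W <- matrix(0, length(cats), ncol(X))
  b <- numeric(length(cats))
  best <- list(f1 = -Inf, W = W, b = b, epoch = 0L)
  history <- numeric(cfg$epochs)
  Xval <- .bow_features(val$texts, vocab, stops)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        Xi <- X[idx, , drop = FALSE]
        P <- .sigmoid(Xi %*% t(W) + matrix(b, length(idx), length(cats), byrow = TRUE))
        E <- P - Y[idx, , drop = FALSE]
        W <- W - cfg$lr_linear * (t(E) %*% Xi / length(idx))
        b <- b - cfg$lr_linear * colMeans(E)
      }
      Pv <- .sigmoid(Xval %*% t(W) + matrix(b, nrow(Xval), length(cats), byrow = TRUE))
      predv <- apply(Pv, 1, function(p) cats[p > 0.5], simplify = FALSE)
      f1 <- macro_f1(predv, val$labels, cats)
      history[epoch] <- f1
      if (f1 > best$f1) best <- list(f1 = f1, W = W, b = b, epoch = epoch)
    }
  })
  structure(
    list(W = best$W, b = best$b, vocab = vocab, threshold = 0.5,
         categories = cats, config = cfg, stops = stops,
         val_history = history, best_epoch = best$epoch),
    class = "ndkg_multilabel"
  )
}

#' Category membership probabilities
#'
#' @param model an `ndkg_multilabel`.
#' @param texts character vector.
#' @return n x 5 matrix of sigmoid probabilities in [0, 1].
#' @export
predict_proba <- function(model, texts) {
  X <- .bow_features(texts, model$vocab, model$stops)
  P <- .sigmoid(X %*% t(model$W) +
                  matrix(model$b, nrow(X), length(model$categories), byrow = TRUE))
  colnames(P) <- model$categories
  P
}

#' Tune the decision threshold on the validation set
#'
#' Evaluates validation macro F1 at the eleven thresholds 0.0, 0.1, ...,
#' 1.0 and returns the argmax; ties are broken by the lowest threshold.
#'
#' @param model an `ndkg_multilabel`.
#' @param val an `ndkg_labeled` validation set.
#' @return the selected threshold, with the full grid of scores in
#'   `attr(, "grid")`.
#' @export
select_threshold <- function(model, val) {
  grid <- seq(0, 1, by = 0.1)
  P <- predict_proba(model, val$texts)
  scores <- vapply(grid, function(th) {
    pred <- apply(P, 1, function(p) model$categories[p > th], simplify = FALSE)
    macro_f1(pred, val$labels, model$categories)
  }, numeric(1))
  out <- grid[which.max(scores)]
  attr(out, "grid") <- data.frame(threshold = grid, macro_f1 = scores)
  out
}

#' Predict category memberships for one document
#'
#' @param model an `ndkg_multilabel` (with `threshold` set).
#' @param text document text.
#' @return character vector of categories with probability strictly above
#'   the threshold (possibly empty).
#' @export
predict_categories <- function(model, text) {
  p <- predict_proba(model, text)[1, ]
  model$categories[p > model$threshold]
}

# --- intent classification --------------------------------------------

#' Wrap a scorer function as an intent model
#'
#' @param scorer function mapping a text to a probability vector over
#'   `categories` (normalized or not).
#' @param categories category order (default [behavior_categories()]).
#' @return object of class `ndkg_intent`.
#' @export
intent_model <- function(scorer, categories = behavior_categories()) {
  structure(list(type = "custom", scorer = scorer, categories = categories),
            class = "ndkg_intent")
}

#' Train the challenging-behavior intent classifier
#'
#' Linear bag-of-words softmax over the ten categories, full-batch gradient
#' descent on the cross entropy. Intended for training on behavior-lexicon
#' phrases or synthetic utterances.
#'
#' @param texts training utterances.
#' @param labels one category per utterance.
#' @param categories category order.
#' @param iters gradient steps.
#' @param lr step size.
#' @param stops stop list.
#' @return object of class `ndkg_intent`.
#' @export
train_intent <- function(texts, labels, categories = behavior_categories(),
                         iters = 300, lr = 0.5, stops = ndkg_stopwords()) {
  stopifnot(all(labels %in% categories))
  vocab <- .bow_vocab(texts, stops)
  X <- cbind(1, .bow_features(texts, vocab, stops))
  Y <- outer(labels, categories, `==`) * 1
  W <- matrix(0, ncol(X), length(categories))
  for (i in seq_len(iters)) {
    Z <- X %*% W
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z) / rowSums(exp(Z))
    W <- W - lr * (t(X) %*% (P - Y) / nrow(X))
  }
  structure(list(type = "linear", W = W, vocab = vocab,
                 categories = categories, stops = stops),
            class = "ndkg_intent")
}

#' Intent probabilities for a text
#'
#' @param model an `ndkg_intent`.
#' @param text input text.
#' @return named probability vector over the model's categories.
#' @export
predict_intent_proba <- function(model, text) {
  p <- if (model$type == "custom") {
    as.numeric(model$scorer(text))
  } else {
    x <- c(1, .bow_features(text, model$vocab, model$stops)[1, ])
    z <- as.numeric(x %*% model$W)
    z <- z - max(z)
    exp(z) / sum(exp(z))
  }
  if (length(p) != length(model$categories)) {
    stop_ndkg("scorer returned ", length(p), " values for ",
              length(model$categories), " categories")
  }
  s <- sum(p)
  if (s > 0) p <- p / s
  names(p) <- model$categories
  p
}

#' Classify the intent of a user query
#'
#' Argmax over the category distribution; ties are broken by the lowest
#' category index (the order of [behavior_categories()]).
#'
#' @param model an `ndkg_intent`.
#' @param text non-empty query text.
#' @return one category name.
#' @export
classify_intent <- function(model, text) {
  stopifnot(nzchar(text))
  p <- predict_intent_proba(model, text)
  model$categories[which.max(p)]
}

#' Intent model trained on a behavior lexicon
#'
#' Uses the BEHAVIOR entries of a lexicon (surface forms labeled with their
#' category) as training utterances.
#'
#' @param entries lexicon data frame (see [read_lexicon()]).
#' @param ... passed to [train_intent()].
#' @return an `ndkg_intent`.
#' @export
intent_model_from_lexicon <- function(entries, ...) {
  entries <- validate_lexicon(entries)
  beh <- entries[entries$vocab == "BEHAVIOR", , drop = FALSE]
  if (!nrow(beh)) stop_ndkg("lexicon has no BEHAVIOR entries")
  train_intent(beh$surface, beh$behavior_category, ...)
}
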