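# Latent Dirichlet allocation fitted by online variational Bayes
# (stochastic natural-gradient updates on the topic-word variational
# parameter lambda, per-document coordinate ascent on gamma). The
# hyperparameter surface mirrors the scikit-learn LatentDirichletAllocation
# defaults used by the pipeline: 10 passes, online updates, learning decay
# 0.7, batch size 128, 50,000 vocabulary features, symmetric priors 1/K.

#' LDA configuration
#'
#' @param max_iter full passes over the corpus (default 10).
#' @param learning update scheme; only `"online"` is implemented.
#' @param learning_decay exponent kappa of the learning-rate schedule
#'   `rho_t = (learning_offset + t)^(-kappa)` (default 0.7).
#' @param batch_size documents per online update (default 128).
#' @param max_features vocabulary cap for [build_count_matrix()] (default 50000).
#' @param seed RNG seed; every stochastic fit takes an explicit seed.
#' @param learning_offset tau0 of the learning-rate schedule (default 10).
#' @param doc_topic_prior alpha; default 1/K.
#' @param topic_word_prior eta; default 1/K.
#' @param max_doc_iter cap on per-document gamma iterations (default 100).
#' @param mean_change_tol convergence tolerance on gamma (default 1e-3).
#' @param n_init random restarts; the fit with the highest in-sample token
#'   log-likelihood is kept (restart seeds derive from `seed`).
#' @return list of class `ndkg_lda_config`.
#' @export
lda_config <- function(max_iter = 10, learning = "online",
                       learning_decay = 0.7, batch_size = 128,
                       max_features = 50000, seed = 1,
                       learning_offset = 10, doc_topic_prior = NULL,
                       topic_word_prior = NULL, max_doc_iter = 100,
                       mean_change_tol = 1e-3, n_init = 3) {
  stopifnot(identical(learning, "online"))
  structure(
    list(max_iter = max_iter, learning = learning,
         learning_decay = learning_decay, batch_size = batch_size,
         max_features = max_features, seed = seed,
         learning_offset = learning_offset,
         doc_topic_prior = doc_topic_prior,
         topic_word_prior = topic_word_prior,
         max_doc_iter = max_doc_iter, mean_change_tol = mean_change_tol,
         n_init = n_init),
    class = "ndkg_lda_config"
  )
}

#' Build a document-term count matrix
#'
#' Vocabulary = the `max_features` most frequent unigrams by total corpus
#' count, ties broken lexicographically. Counts are raw token counts;
#' documents with no in-vocabulary tokens keep an all-zero row.
#'
#' @param streams named list of token streams.
#' @param max_features vocabulary size cap.
#' @return list of class `ndkg_dtm`: `docs`, `vocab`, `counts`
#'   (docs x vocab integer matrix with dimnames).
#' @export
build_count_matrix <- function(streams, max_features = 50000) {
  if (!length(streams)) stop_ndkg("empty corpus")
  docs <- vapply(streams, function(s) s$doc_id, character(1))
  all_tokens <- unlist(lapply(streams, `[[`, "tokens"), use.names = FALSE)
  if (!length(all_tokens)) stop_ndkg("no tokens in corpus")
  totals <- table(all_tokens)
  ord <- order(-as.integer(totals), names(totals))
  vocab <- names(totals)[ord][seq_len(min(max_features, length(totals)))]
  vocab_sorted <- sort(vocab)
  counts <- matrix(0L, length(streams), length(vocab_sorted),
                   dimnames = list(docs, vocab_sorted))
  for (i in seq_along(streams)) {
    tt <- table(streams[[i]]$tokens)
    tt <- tt[names(tt) %in% vocab_sorted]
    if (length(tt)) counts[i, names(tt)] <- as.integer(tt)
  }
  structure(list(docs = docs, vocab = vocab_sorted, counts = counts),
            class = "ndkg_dtm")
}

dirichlet_expectation <- function(m) {
  digamma(m) - digamma(rowSums(m))
}

# Per-document variational E-step. Returns the gamma matrix and the
# sufficient statistics for the lambda update. During training gamma is
# initialized from gamma noise (useful annealing while topics
# differentiate); the final inference pass uses a constant init so that
# identical documents receive identical topic assignments.
.lda_e_step <- function(X, expElogbeta, alpha, cfg, final = FALSE) {
  D <- nrow(X); K <- nrow(expElogbeta); V <- ncol(expElogbeta)
  gamma <- if (final) matrix(1, D, K) else
    matrix(rgamma(D * K, 100, rate = 100), D, K)
  sstats <- matrix(0, K, V)
  for (d in seq_len(D)) {
    ids <- which(X[d, ] > 0)
    if (!length(ids)) {
      gamma[d, ] <- alpha
      next
    }
    cts <- X[d, ids]
    gammad <- gamma[d, ]
    expElogthetad <- exp(digamma(gammad) - digamma(sum(gammad)))
    eb <- expElogbeta[, ids, drop = FALSE]
    for (it in seq_len(cfg$max_doc_iter)) {
      phinorm <- as.vector(crossprod(eb, expElogthetad)) + 1e-100
      gammad_new <- alpha + expElogthetad * as.vector(eb %*% (cts / phinorm))
      change <- mean(abs(gammad_new - gammad))
      gammad <- gammad_new
      expElogthetad <- exp(digamma(gammad) - digamma(sum(gammad)))
      if (change < cfg$mean_change_tol) break
    }
    gamma[d, ] <- gammad
    phinorm <- as.vector(crossprod(eb, expElogthetad)) + 1e-100
    sstats[, ids] <- sstats[, ids] + outer(expElogthetad, cts / phinorm)
  }
  list(gamma = gamma, sstats = sstats * expElogbeta)
}

#' Fit LDA by online variational Bayes
#'
#' Deterministic given `cfg$seed`. Runs `cfg$n_init` restarts from seeds
#' derived from `cfg$seed` and keeps the fit with the highest in-sample
#' token log-likelihood (online variational Bayes is multimodal; the
#' likelihood reliably separates merged-topic optima from good ones).
#' Returns row-stochastic theta (document-topic) and phi (topic-word)
#' matrices.
#'
#' @param cm an `ndkg_dtm` from [build_count_matrix()].
#' @param K number of topics (2 <= K <= number of documents).
#' @param cfg an `ndkg_lda_config`.
#' @return object of class `ndkg_lda`: `K`, `theta` (docs x K, rows sum to
#'   1), `phi` (K x vocab, rows sum to 1), `vocab`, `docs`, `loglik`,
#'   `config`.
#' @export
fit_lda <- function(cm, K, cfg = lda_config()) {
  stopifnot(inherits(cm, "ndkg_dtm"))
  if (K < 2) stop_ndkg("K must be >= 2")
  D <- nrow(cm$counts)
  if (K > D) stop_ndkg("K (", K, ") exceeds the number of documents (", D, ")")
  best <- NULL
  for (r in seq_len(max(1, cfg$n_init))) {
    seed_r <- (cfg$seed + (r - 1) * 104729) %% 2147483647
    fit <- .fit_lda_once(cm, K, cfg, seed_r)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

.fit_lda_once <- function(cm, K, cfg, seed) {
  D <- nrow(cm$counts); V <- ncol(cm$counts)
  alpha <- cfg$doc_topic_prior %||% (1 / K)
  eta <- cfg$topic_word_prior %||% (1 / K)
  res <- with_seed(seed, {
    # initialize lambda from a random partition of the documents (plus
    # gamma noise): topics start from real co-occurrence structure, which
    # breaks symmetry far more reliably than noise alone
    lambda <- matrix(rgamma(K * V, 100, rate = 100), K, V)
    part <- sample(rep_len(seq_len(K), D))
    for (k in seq_len(K)) {
      dk <- which(part == k)
      lambda[k, ] <- lambda[k, ] +
        colSums(cm$counts[dk, , drop = FALSE]) * (K / D)
    }
    expElogbeta <- exp(dirichlet_expectation(lambda))
    batches <- split(seq_len(D), ceiling(seq_len(D) / cfg$batch_size))
    t_up <- 0
    for (epoch in seq_len(cfg$max_iter)) {
      for (b in batches) {
        e <- .lda_e_step(cm$counts[b, , drop = FALSE], expElogbeta, alpha, cfg)
        rho <- (cfg$learning_offset + t_up)^(-cfg$learning_decay)
        lambda <- (1 - rho) * lambda +
          rho * (eta + (D / length(b)) * e$sstats)
        expElogbeta <- exp(dirichlet_expectation(lambda))
        t_up <- t_up + 1
      }
    }
    final <- .lda_e_step(cm$counts, expElogbeta, alpha, cfg, final = TRUE)
    list(lambda = lambda, gamma = final$gamma)
  })
  theta <- res$gamma / rowSums(res$gamma)
  phi <- res$lambda / rowSums(res$lambda)
  dimnames(theta) <- list(cm$docs, NULL)
  dimnames(phi) <- list(NULL, cm$vocab)
  nz <- which(cm$counts > 0, arr.ind = TRUE)
  pred <- theta %*% phi
  ll <- sum(cm$counts[nz] * log(pred[nz] + 1e-300))
  structure(list(K = K, theta = theta, phi = phi, vocab = cm$vocab,
                 docs = cm$docs, loglik = ll, config = cfg),
            class = "ndkg_lda")
}

#' @export
print.ndkg_lda <- function(x, ...) {
  cat("<ndkg_lda>", x$K, "topics,", length(x$docs), "documents,",
      length(x$vocab), "terms\n")
  invisible(x)
}

#' Top words of each topic
#'
#' @param model an `ndkg_lda`.
#' @param n words per topic.
#' @return character matrix, one row per topic.
#' @export
top_words <- function(model, n = 10) {
  t(apply(model$phi, 1, function(p) {
    model$vocab[order(-p)][seq_len(min(n, length(p)))]
  }))
}

#' Dominant topic of each document
#'
#' Argmax over a normalized theta row (or each row of a matrix); ties are
#' broken by the lowest topic index.
#'
#' @param theta numeric vector or docs x K matrix.
#' @return integer topic index (1-based), vectorized over rows.
#' @export
dominant_topic <- function(theta) {
  if (is.matrix(theta)) return(max.col(theta, ties.method = "first"))
  which.max(theta)
}
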