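# Hierarchical topic modeling: fit LDA on the corpus, hard-assign each
# document to its dominant topic, and recursively re-fit LDA inside every
# topic holding more than `threshold` documents. Recursion stops when all
# topics are at or below the threshold, when a topic swallows its node's
# entire document set (no progress), or at a depth cap. Only the leaf
# topics -- the lowest level of the hierarchy -- feed the knowledge graph.
#
# The topic count of a child node is K_child = max(2, ceiling(n/threshold))
# so that expected leaf size tracks the threshold and recursion shrinks the
# problem at every level.

#' Hierarchical topic model
#'
#' @param streams named list of token streams (whole corpus or subset).
#' @param K0 topic count of the root LDA (e.g. 200 for an 80k-page corpus
#'   subset, 300 for a 120k-page subset, proportional to size).
#' @param threshold maximum documents per topic before the topic is
#'   re-modeled (300 in the reference configuration).
#' @param cfg an [lda_config()]; child nodes derive their seeds from
#'   `cfg$seed` deterministically.
#' @param depth_cap last-resort recursion bound (default 10).
#' @return root node of class `ndkg_htm_node`: `node_id`, `doc_ids`,
#'   `model` (`ndkg_lda`), `K`, `assign` (named topic index per doc),
#'   `children` (list indexed by topic), `is_leaf_topic`, `no_progress`,
#'   `capped` (per-topic logicals), `depth`.
#' @export
hierarchical_topic_model <- function(streams, K0, threshold, cfg = lda_config(),
                                     depth_cap = 10) {
  stopifnot(K0 >= 2, threshold >= 1)
  if (length(streams) < 2) stop_ndkg("need at least 2 documents")
  counter <- new.env()
  counter$n <- 0L
  .htm_build(streams, min(K0, length(streams)), threshold, cfg, depth_cap,
             depth = 1L, counter = counter)
}

.htm_build <- function(streams, K, threshold, cfg, depth_cap, depth, counter) {
  counter$n <- counter$n + 1L
  node_id <- sprintf("n%d", counter$n)
  cm <- build_count_matrix(streams, cfg$max_features)
  node_cfg <- cfg
  node_cfg$seed <- (cfg$seed + 7919L * counter$n) %% 2147483647L
  model <- fit_lda(cm, K, node_cfg)
  assign <- dominant_topic(model$theta)
  names(assign) <- model$docs
  children <- vector("list", K)
  is_leaf <- rep(TRUE, K)
  no_progress <- rep(FALSE, K)
  capped <- rep(FALSE, K)
  for (k in seq_len(K)) {
    members <- model$docs[assign == k]
    if (length(members) <= threshold) next
    if (length(members) == length(model$docs)) {
      no_progress[k] <- TRUE            # topic swallowed the whole node
      next
    }
    if (depth >= depth_cap) {
      capped[k] <- TRUE
      next
    }
    K_child <- max(2, ceiling(length(members) / threshold))
    K_child <- min(K_child, length(members))
    children[[k]] <- .htm_build(streams[members], K_child, threshold, cfg,
                                depth_cap, depth + 1L, counter)
    is_leaf[k] <- FALSE
  }
  structure(
    list(node_id = node_id, doc_ids = model$docs, model = model, K = K,
         assign = assign, children = children, is_leaf_topic = is_leaf,
         no_progress = no_progress, capped = capped, depth = depth),
    class = "ndkg_htm_node"
  )
}

#' @export
print.ndkg_htm_node <- function(x, ...) {
  cat("<ndkg_htm_node>", x$node_id, "-", length(x$doc_ids), "docs,",
      x$K, "topics,", sum(!x$is_leaf_topic), "recursed\n")
  invisible(x)
}

#' All nodes of a topic hierarchy
#'
#' @param root an `ndkg_htm_node`.
#' @return flat list of nodes (preorder).
#' @export
htm_nodes <- function(root) {
  out <- list(root)
  for (ch in root$children) {
    if (!is.null(ch)) out <- c(out, htm_nodes(ch))
  }
  out
}

#' Leaf topics of a hierarchy
#'
#' Returns every topic not recursed into, labeled `T<node>.<index>`, with
#' its member documents, the members' node-local theta weight for that
#' topic (the belongsToTopic weights), and the topic's phi row over the
#' node vocabulary (the describedBy weights). By hard dominant-topic
#' assignment every document belongs to exactly one leaf topic, so leaf
#' document sets partition the corpus.
#'
#' @param root an `ndkg_htm_node`.
#' @return list of leaves; each has `label`, `node_id`, `topic`, `doc_ids`,
#'   `theta` (named numeric over members), `phi` (named numeric over the
#'   node vocabulary), `no_progress`, `capped`.
#' @export
leaf_topics <- function(root) {
  out <- list()
  for (node in htm_nodes(root)) {
    for (k in seq_len(node$K)) {
      if (!node$is_leaf_topic[k]) next
      members <- node$doc_ids[node$assign == k]
      th <- node$model$theta[match(members, node$doc_ids), k]
      names(th) <- members
      ph <- node$model$phi[k, ]
      out[[length(out) + 1L]] <- list(
        label = sprintf("T%s.%d", node$node_id, k),
        node_id = node$node_id, topic = k, doc_ids = members,
        theta = th, phi = ph,
        no_progress = node$no_progress[k], capped = node$capped[k]
      )
    }
  }
  out
}

#' Document-unigram weights as the theta-phi product
#'
#' The containsNgram weight matrix: matrix product of the document-topic
#' weights (theta) and topic-word weights (phi). Row-stochasticity is
#' preserved: each output row sums to 1.
#'
#' @param theta docs x K row-stochastic matrix.
#' @param phi K x vocab row-stochastic matrix.
#' @return docs x vocab matrix `theta %*% phi`.
#' @export
contains_ngram_weights <- function(theta, phi) {
  if (!is.matrix(theta)) theta <- matrix(theta, nrow = 1)
  if (ncol(theta) != nrow(phi)) {
    stop_ndkg("shape mismatch: theta has ", ncol(theta),
              " topics, phi has ", nrow(phi))
  }
  theta %*% phi
}
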